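test_that("strategy pooling tallies match brute-force counts", {
  labs <- data.frame(category = c("A", "A", "B", "E", "F", "H", "J", "J"))
  freq <- pool_strategies(labs)
  expect_equal(sum(freq$n), nrow(labs))
  expect_equal(freq$n[freq$category == "A"], 2)
  by_pool <- tapply(freq$n, freq$pooled, sum)
  expect_equal(as.vector(by_pool[c("direct", "indirect", "non_effective")]),
               c(3L, 2L, 3L))

  set.seed(15)
  rand <- data.frame(
    category = sample(LETTERS[1:10], 200, replace = TRUE),
    day = sample(1:3, 200, replace = TRUE)
  )
  freq2 <- pool_strategies(rand, day)
  for (d in 1:3) {
    sub <- rand[rand$day == d, ]
    for (ct in LETTERS[1:10]) {
      expect_equal(freq2$n[freq2$day == d & freq2$category == ct],
                   sum(sub$category == ct))
    }
  }
  # empty input yields a clean zero table
  empty <- pool_strategies(data.frame(category = character(0)))
  expect_equal(sum(empty$n), 0)
})

test_that("pooled chi-square matches hand computation and degenerate cases", {
  a <- data.frame(category = rep(c("A", "E", "H"), times = c(5, 3, 2)))
  ht0 <- chi_square_pooled(a, a)
  expect_equal(ht0$statistic, 0)
  expect_equal(ht0$p.value, 1)

  # [[10,0,0],[0,10,0]] with a zero-margin class dropped:
  # 2x2 table with all expected counts 5 -> X2 = 4 * 25/5 = 20, df 1
  g1 <- data.frame(category = rep("A", 10))
  g2 <- data.frame(category = rep("E", 10))
  expect_warning(ht <- chi_square_pooled(g1, g2), "zero-margin")
  expect_equal(ht$statistic, 20)
  expect_equal(ht$df, 1)
  expect_equal(ht$dropped, "non_effective")

  # swapping the groups leaves the statistic unchanged
  b <- data.frame(category = rep(c("B", "F", "I"), times = c(2, 6, 2)))
  expect_equal(chi_square_pooled(a, b)$statistic,
               chi_square_pooled(b, a)$statistic)
})

test_that("Cohen's kappa matches hand formula and an independent implementation", {
  expect_equal(cohens_kappa(c("A", "B", "B"), c("A", "B", "B"))$kappa, 1)

  # contrived 2x2 table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  r1 <- rep(c("x", "x", "y", "y"), times = c(20, 5, 10, 15))
  r2 <- rep(c("x", "y", "x", "y"), times = c(20, 5, 10, 15))
  expect_equal(cohens_kappa(r1, r2)$kappa, 0.4)

  # independent uniform raters agree only by chance
  set.seed(16)
  u1 <- sample(LETTERS[1:5], 1e4, replace = TRUE)
  u2 <- sample(LETTERS[1:5], 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(u1, u2)$kappa), 0.05)

  # cross-check against e1071 on random confusion structures
  for (i in 1:5) {
    v1 <- sample(LETTERS[1:4], 300, replace = TRUE)
    v2 <- ifelse(stats::runif(300) < 0.6, v1, sample(LETTERS[1:4], 300, replace = TRUE))
    ours <- cohens_kappa(v1, v2)$kappa
    ref <- e1071::classAgreement(table(v1, v2))$kappa
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  # invariance under consistent relabeling
  map <- c(A = "Q", B = "R", C = "S", D = "T")
  expect_equal(cohens_kappa(map[v1], map[v2])$kappa, cohens_kappa(v1, v2)$kappa)
})

test_that("parameter-wise agreement mirrors the three-parameter structure", {
  set.seed(17)
  truth <- sample(LETTERS[1:10], 80, replace = TRUE)
  agr <- agreement_by_parameter(truth, truth)
  expect_equal(agr$kappa, rep(1, 4))
  # a rater who only confuses B with C keeps effectivity and
  # directionality agreement perfect
  other <- ifelse(truth == "B", "C", truth)
  agr2 <- agreement_by_parameter(truth, other)
  expect_equal(agr2$kappa[agr2$parameter == "effectiveness"], 1)
  expect_equal(agr2$kappa[agr2$parameter == "directionality"], 1)
  expect_lt(agr2$kappa[agr2$parameter == "precision"], 1)
})

test_that("Mann-Whitney U uses midranks and matches a permutation oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  mw <- mann_whitney_u(x, y)
  expect_equal(mw$U, length(x) * length(y) / 2) # identical samples
  expect_gt(mw$p.value, 0.9)

  set.seed(18)
  a <- stats::rnorm(8, 0, 1); b <- stats::rnorm(8, 1.2, 1)
  mw2 <- mann_whitney_u(a, b)
  # Monte-Carlo permutation oracle on the rank-sum statistic
  pooled <- c(a, b); n1 <- length(a)
  obs <- abs(mw2$U - n1 * length(b) / 2)
  perm <- replicate(4000, {
    idx <- sample(length(pooled), n1)
    r <- rank(pooled)
    abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - n1 * length(b) / 2)
  })
  p_perm <- mean(perm >= obs - 1e-9)
  expect_lt(abs(mw2$p.value - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("Friedman with Bonferroni behaves on degenerate and shifted data", {
  const <- matrix(5, nrow = 6, ncol = 4)
  fr <- friedman_bonferroni(const)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$pairwise$p.adjusted, rep(1, 6))

  set.seed(19)
  m <- sapply(c(0, 0.5, 1.5), function(mu) stats::rnorm(8, mu))
  fr2 <- friedman_bonferroni(m)
  expect_true(all(fr2$pairwise$p.adjusted >= fr2$pairwise$p.raw))
  expect_true(all(fr2$pairwise$p.adjusted <= 1))
  # invariant under permuting the condition order
  fr3 <- friedman_bonferroni(m[, c(3, 1, 2)])
  expect_equal(fr3$statistic, fr2$statistic)

  expect_error(friedman_bonferroni(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("normality screening flags heavy departures only", {
  set.seed(20)
  norm_p <- ks_normality(stats::rnorm(100))$p.value
  unif_p <- ks_normality(stats::runif(300))$p.value
  expect_gt(norm_p, 0.01)
  expect_lt(unif_p, 0.01)
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("summaries report medians with interquartile ranges per group", {
  cfg <- pool_config()
  sp <- cohort_spec("young", n_rats = 1, days = 2, trials_per_day = 2, seed = 31)
  co <- generate_cohort(sp, cfg)
  mets <- trials_metrics(co, cfg)
  labs <- classify_trials(co, cfg)
  rep <- summarize_trials(mets, labs, group, day)
  expect_true(all(c("metric", "median", "q1", "q3", "n") %in%
                    names(rep$metric_summary)))
  one <- rep$metric_summary[rep$metric_summary$day == 1 &
                              rep$metric_summary$metric == "mean_speed", ]
  expect_equal(one$median,
               stats::median(mets$mean_speed[mets$day == 1]))
  expect_equal(sum(rep$strategy_frequencies$n), nrow(labs))
})
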