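cfg <- pool_config()

test_that("construction ground truth is reproducible and feasibility-checked", {
  sp <- archetype_spec("F", seed = 99)
  g1 <- generate_archetype(sp, cfg)
  g2 <- generate_archetype(sp, cfg)
  expect_identical(g1$track$x, g2$track$x)
  expect_identical(g1$truth, g2$truth)

  expect_error(archetype_spec("B", n_curves = 5), "requires")
  expect_error(archetype_spec("H", n_curves = 2), "not constructible")
  expect_error(archetype_spec("G", n_curves = 5, n_peripheral = 5), "infeasible")
  expect_error(archetype_spec("A", start_octant = 1), "start_octant")
})

test_that("generated trials stay in the pool and inside the trial duration", {
  set.seed(12)
  for (ct in LETTERS[1:10]) {
    gen <- generate_archetype(archetype_spec(ct, start_octant = sample(3:7, 1)), cfg)
    r <- sqrt(gen$track$x^2 + gen$track$y^2)
    expect_lte(max(r), pool_radius(cfg) + cfg$wall_tolerance)
    expect_lte(max(gen$track$t), 90 + 1e-9)
    expect_gte(min(gen$track$t), 0)
  }
})

test_that("the classifier recovers construction ground truth on random noise-free specs", {
  set.seed(13)
  n_ok <- 0; n <- 40
  for (r in 1:n) {
    ct <- sample(LETTERS[1:7], 1)
    band <- swimstrat:::category_band(ct)
    total <- sample(band[1]:min(band[2], 8), 1)
    nz <- if (total >= 1) stats::rbinom(1, 1, 0.4) else 0
    ns <- if (total - nz >= 1) stats::rbinom(1, 1, 0.3) else 0
    np <- if (total - nz - ns >= 1 && total <= 4) stats::rbinom(1, 1, 0.4) else 0
    sp <- archetype_spec(ct, n_curves = total - nz - ns - np, n_zigzags = nz,
                         n_spirals = ns, n_peripheral = np,
                         start_octant = sample(3:7, 1), noise_sd = 0)
    gen <- generate_archetype(sp, cfg)
    lab <- ssa_classify(gen$track, cfg)
    if (as.character(lab$category) == ct &&
        lab$n_changes == gen$truth$n_changes) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, n)
})

test_that("category recovery stays high under realistic tracking noise", {
  # 0.5 cm Gaussian jitter per sample; threshold below documents the
  # measured operating point of the default preprocessing
  recovery_threshold <- 0.85
  set.seed(14)
  n_ok <- 0; n <- 60
  for (r in 1:n) {
    ct <- sample(LETTERS[1:10], 1)
    band <- swimstrat:::category_band(ct)
    k <- if (ct %in% LETTERS[1:7]) sample(band[1]:min(band[2], 8), 1) else NA
    sp <- archetype_spec(ct, n_curves = k, start_octant = sample(3:7, 1),
                         noise_sd = 0.5)
    gen <- generate_archetype(sp, cfg)
    if (as.character(ssa_classify(gen$track, cfg)$category) == ct) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, recovery_threshold)
})

test_that("cohort simulation is reproducible and honours its mixtures", {
  all_a <- matrix(0, nrow = 2, ncol = 10, dimnames = list(NULL, LETTERS[1:10]))
  all_a[, "A"] <- 1
  sp <- cohort_spec("young", n_rats = 2, days = 2, trials_per_day = 2,
                    mixtures = all_a, seed = 7)
  co <- generate_cohort(sp, cfg, labels_only = TRUE)
  expect_true(all(co$category == "A"))
  expect_equal(nrow(co), 8)

  sp2 <- cohort_spec("aged", n_rats = 3, days = 3, seed = 21)
  l1 <- generate_cohort(sp2, labels_only = TRUE)
  l2 <- generate_cohort(sp2, labels_only = TRUE)
  expect_identical(l1, l2)

  expect_error(cohort_spec("young", mixtures = matrix(1, 2, 10), days = 2),
               "sum to 1")
})

test_that("default cohort mixtures produce a detectable group difference late in training", {
  # label-layer power check: pooled chi-square on the last acquisition day
  rej <- 0; n_rep <- 40
  for (r in 1:n_rep) {
    y <- generate_cohort(cohort_spec("young", seed = 3000 + r), labels_only = TRUE)
    a <- generate_cohort(cohort_spec("aged", seed = 7000 + r), labels_only = TRUE)
    ht <- suppressWarnings(chi_square_pooled(y[y$day == 10, ], a[a$day == 10, ]))
    if (ht$p.value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.9)
})

test_that("track files round-trip through write_tracks/read_tracks byte-stably", {
  sp <- cohort_spec("young", n_rats = 1, days = 1, trials_per_day = 3, seed = 5)
  co <- generate_cohort(sp, cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_tracks(co, dir1)
  write_tracks(co, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines)) # byte-stable

  back <- read_tracks(dir1, cfg = cfg)
  expect_equal(nrow(back), 3)
  expect_equal(back$category, co$category)
  for (i in 1:3) {
    expect_lt(max(abs(back$track[[i]]$x - co$track[[i]]$x)), 1e-6)
  }
  # reclassification of the round-tripped tracks matches the originals
  expect_equal(classify_trials(back, cfg)$category,
               classify_trials(co, cfg)$category)
})
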