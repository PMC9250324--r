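#' Strategy frequency tables with pooling
#'
#' Tallies search-strategy categories per grouping key and attaches the
#' pooled class used in group comparisons: direct (A-D), indirect (E-G),
#' and non-effective (H-J). Zero counts are kept so tables from different
#' groups are always conformable.
#'
#' @param labels A data frame with a `category` column (A-J), e.g. from
#'   [classify_trials()] or [generate_cohort()].
#' @param ... Grouping columns (tidy-select), e.g. `group, day`.
#' @return A tibble: grouping keys, `category`, `pooled`, `n`.
#' @export
pool_strategies <- function(labels, ...) {
  stopifnot("category" %in% names(labels))
  keys <- dplyr::select(labels, ...)
  df <- dplyr::bind_cols(keys, tibble::tibble(
    category = factor(as.character(labels$category), levels = LETTERS[1:10])
  ))
  out <- dplyr::count(df, dplyr::across(dplyr::everything()), .drop = FALSE)
  if (ncol(keys) > 0) {
    # drop key combinations that never occur, keep all categories within them
    seen <- dplyr::distinct(dplyr::select(df, -"category"))
    out <- dplyr::semi_join(out, seen, by = names(keys))
  }
  out$pooled <- strategy_parameters(as.character(out$category))$pooled
  dplyr::relocate(out, "pooled", .after = "category")
}

#' Chi-square comparison of pooled strategy distributions
#'
#' Pearson chi-square (no continuity correction by default) on the
#' groups-by-classes contingency table of pooled strategy counts, the
#' comparison used for strategy frequencies between cohorts. Classes with a
#' zero margin are dropped with a warning and the degrees of freedom
#' adjusted. `by = "category"` tests the full A-J distribution instead of
#' the three pooled classes.
#'
#' @param f1,f2 Frequency tables from [pool_strategies()] (or data frames
#'   with `category` columns, which are tallied first).
#' @param by `"pooled"` (default) or `"category"`.
#' @param correct Apply Yates' continuity correction (only meaningful for
#'   2x2 tables).
#' @return A list of class `chi_square_pooled`: `statistic`, `df`,
#'   `p.value`, `observed`, `expected`, `dropped` (classes removed for zero
#'   margins).
#' @examples
#' a <- data.frame(category = c("A", "A", "B", "E"))
#' b <- data.frame(category = c("E", "F", "H", "J"))
#' chi_square_pooled(a, b)$p.value
#' @export
chi_square_pooled <- function(f1, f2, by = c("pooled", "category"),
                              correct = FALSE) {
  by <- match.arg(by)
  counts_of <- function(f) {
    if (!all(c("category", "n") %in% names(f))) f <- pool_strategies(f)
    grp <- dplyr::summarise(dplyr::group_by(f, .data[[by]]),
                            n = sum(.data$n), .groups = "drop")
    stats::setNames(grp$n, as.character(grp[[by]]))
  }
  c1 <- counts_of(f1); c2 <- counts_of(f2)
  classes <- union(names(c1), names(c2))
  tab <- rbind(
    c1[match(classes, names(c1))],
    c2[match(classes, names(c2))]
  )
  tab[is.na(tab)] <- 0
  colnames(tab) <- classes
  rownames(tab) <- c("group1", "group2")
  zero <- colSums(tab) == 0
  dropped <- colnames(tab)[zero]
  if (any(zero)) {
    warning("dropping zero-margin class(es): ", paste(dropped, collapse = ", "),
            "; df adjusted")
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("fewer than 2 non-empty classes; nothing to compare", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, observed = tab, expected = ht$expected,
         dropped = dropped, method = ht$method),
    class = "chi_square_pooled"
  )
}

#' @export
print.chi_square_pooled <- function(x, ...) {
  cat(sprintf("Chi-square on pooled strategies: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(x$observed)
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with the
#' expected agreement p_e from the raters' marginal distributions. Used to
#' quantify inter- and intra-observer reliability of strategy labels;
#' identical ratings give kappa = 1 by construction.
#'
#' @param r1,r2 Category vectors of equal length (factors or characters on
#'   the same label alphabet).
#' @return An `agreement_result`: `kappa`, `n_items`, `p_observed`,
#'   `p_expected`, and the confusion `table`.
#' @examples
#' cohens_kappa(c("A", "B", "B"), c("A", "B", "B"))$kappa # 1
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rating vectors must have equal length", call. = FALSE)
  if (length(r1) == 0) stop("empty ratings", call. = FALSE)
  levels <- sort(union(as.character(r1), as.character(r2)))
  f1 <- factor(as.character(r1), levels = levels)
  f2 <- factor(as.character(r2), levels = levels)
  tab <- table(rater1 = f1, rater2 = f2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) 1 else (po - pe) / (1 - pe)
  structure(
    list(kappa = kappa, n_items = n, p_observed = po, p_expected = pe,
         table = tab),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (n = %d, p_o = %.3f, p_e = %.3f)\n",
              x$kappa, x$n_items, x$p_observed, x$p_expected))
  invisible(x)
}

#' @rdname tidy.ssa_label
#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, n_items = x$n_items,
                 p_observed = x$p_observed, p_expected = x$p_expected)
}

#' Parameter-wise inter-rater agreement
#'
#' Computes Cohen's kappa between two raters' A-J labels on the full
#' classification and on each classification parameter separately
#' (effectiveness, directionality/localization, precision band), mirroring
#' how observer reliability is reported for the strategy algorithm.
#'
#' @param r1,r2 Category vectors (A-J) of equal length.
#' @return A tibble with one row per parameter: `parameter`, `kappa`,
#'   `n_items`.
#' @export
agreement_by_parameter <- function(r1, r2) {
  p1 <- strategy_parameters(r1)
  p2 <- strategy_parameters(r2)
  one <- function(name, a, b) {
    ka <- cohens_kappa(a, b)
    tibble::tibble(parameter = name, kappa = ka$kappa, n_items = ka$n_items)
  }
  dplyr::bind_rows(
    one("category", p1$category, p2$category),
    one("effectiveness", p1$effective, p2$effective),
    one("directionality", p1$directionality, p2$directionality),
    one("precision", dplyr::coalesce(as.character(p1$precision_band), "none"),
        dplyr::coalesce(as.character(p2$precision_band), "none"))
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of a metric between two groups. The U
#' statistic is computed from midranks (ties shared); the p-value comes
#' from the normal approximation with continuity correction
#' ([stats::wilcox.test()]).
#'
#' @param a,b Numeric samples.
#' @return A list: `U`, `p.value`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  )
  list(U = unname(U), p.value = p, n1 = n1, n2 = n2)
}

#' Friedman test with Bonferroni-corrected pairwise post hocs
#'
#' Friedman rank test across repeated conditions (e.g. training days)
#' within subjects, followed by pairwise two-sided Wilcoxon signed-rank
#' tests with Bonferroni correction (raw p multiplied by the number of
#' pairwise comparisons, capped at 1).
#'
#' @param mat A complete numeric matrix, subjects x conditions (no `NA`).
#' @return A list: `statistic`, `df`, `p.value`, and `pairwise` (a tibble
#'   with `cond1`, `cond2`, `p.raw`, `p.adjusted`).
#' @export
friedman_bonferroni <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("Friedman test requires complete blocks (no NA)", call. = FALSE)
  if (ncol(mat) < 2 || nrow(mat) < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  ht <- stats::friedman.test(mat)
  if (is.nan(ht$statistic)) {
    # no rank variance at all (constant blocks): nothing to reject
    ht$statistic[] <- 0
    ht$p.value <- 1
  }
  pairs <- utils::combn(ncol(mat), 2)
  n_comp <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_comp), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- if (all(mat[, i] == mat[, j])) {
      1
    } else {
      suppressWarnings(
        stats::wilcox.test(mat[, i], mat[, j], paired = TRUE, exact = FALSE)$p.value
      )
    }
    tibble::tibble(
      cond1 = colnames(mat)[i] %||% as.character(i),
      cond2 = colnames(mat)[j] %||% as.character(j),
      p.raw = p,
      p.adjusted = min(1, p * n_comp)
    )
  })
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, pairwise = pw)
}

#' Kolmogorov-Smirnov normality check
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test of composite normality
#' (mean and variance estimated from the sample), the standard screen
#' before choosing nonparametric group comparisons.
#'
#' @param x Numeric sample (n >= 5).
#' @return A list: `D`, `p.value`, `n`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  ht <- nortest::lillie.test(x)
  list(D = unname(ht$statistic), p.value = ht$p.value, n = length(x))
}

#' Summary report tables for a set of trials
#'
#' Median and interquartile range of each traditional measure per grouping
#' key, plus the per-key strategy frequency table — the two table families
#' of a standard acquisition/probe report.
#'
#' @param metrics A metrics tibble from [trials_metrics()].
#' @param labels A label tibble with a `category` column (e.g. from
#'   [classify_trials()]).
#' @param ... Grouping columns present in both tables (default `group`,
#'   `day` when present).
#' @return A list of tibbles: `metric_summary` (key columns, `metric`,
#'   `median`, `q1`, `q3`, `n`) and `strategy_frequencies` (from
#'   [pool_strategies()]).
#' @export
summarize_trials <- function(metrics, labels, ...) {
  dots <- rlang::enquos(...)
  if (length(dots) == 0) {
    keys <- intersect(c("group", "day"), names(metrics))
    dots <- rlang::syms(keys)
  }
  metric_cols <- intersect(
    c("platform_latency", "platform_distance", "mean_speed",
      "quadrant_time_pct", "platform_crossings"),
    names(metrics)
  )
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, dplyr::all_of(c(
      vapply(dots, rlang::as_name, character(1)), metric_cols))),
    dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  metric_summary <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c(vapply(dots, rlang::as_name, character(1)), "metric")))),
    median = stats::median(.data$value),
    q1 = unname(stats::quantile(.data$value, 0.25)),
    q3 = unname(stats::quantile(.data$value, 0.75)),
    n = dplyr::n(),
    .groups = "drop"
  )
  freq <- pool_strategies(labels, !!!dots)
  list(metric_summary = metric_summary, strategy_frequencies = freq)
}
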