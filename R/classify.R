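#' Classify one swim trial into a search-strategy category
#'
#' Applies the three-parameter decision tree to a trial:
#' \enumerate{
#'   \item \strong{Effectiveness} — the strategy is effective when the track
#'     ever reaches the platform zone (zone 0).
#'   \item \strong{Initial directionality} (effective trials) — direct when
#'     the first entry into the peripheral platform zone (zone 1, or zone 0
#'     directly) precedes the start of the first trajectory change;
#'     otherwise indirect.
#'   \item \strong{Precision} — the number of trajectory changes committed
#'     before the first zone-0 entry, banded: direct 0 = A, 1-3 = B,
#'     4-6 = C, >= 7 = D; indirect 1-3 = E, 4-6 = F, >= 7 = G.
#' }
#' Ineffective trials are J (thigmotaxis) when the search stayed in the
#' outer pool zone (zone 4, up to a tolerated fraction of excursions), H
#' (localized) when the occupied octants form at most three contiguous
#' sectors, and I (nonlocalized) otherwise. Every valid trajectory receives
#' exactly one of the ten categories.
#'
#' Trajectory changes are the union of curved movements (> 90 degrees of
#' angulation), nonsense movements (zigzags, spirals), and peripheral
#' seeking (see [detect_curves()], [detect_nonsense()],
#' [detect_peripheral()], [merge_events()]).
#'
#' @param track A raw [swim_track()].
#' @param cfg A [pool_config()].
#' @param params A [classifier_params()].
#' @return An `ssa_label` object: a list with `category` (factor, levels
#'   A-J), `effective`, `directionality` (`"direct"`, `"indirect"`,
#'   `"not-applicable"`), `n_changes`, per-kind counts, the `events` tibble
#'   (all detected events, with a `counted` flag), the censoring time
#'   `t_platform` (first zone-0 entry, `NA` when ineffective), and the trial
#'   metadata.
#' @examples
#' cfg <- pool_config()
#' gen <- generate_archetype(archetype_spec("B", noise_sd = 0, seed = 2), cfg)
#' ssa_classify(gen$track, cfg)$category
#' @export
ssa_classify <- function(track, cfg, params = classifier_params()) {
  pp <- preprocess_track(track, params)
  rs <- pp$resampled
  zone <- zone_of(rs$x, rs$y, cfg)
  oct <- octant_of(rs$x, rs$y, cfg)

  events <- merge_events(
    detect_curves(pp$headings, params),
    detect_nonsense(pp$headings, params),
    detect_peripheral(rs, cfg, params)
  )

  effective <- any(zone == 0L)
  t_platform <- if (effective) rs$t[match(0L, zone)] else NA_real_
  t_arrival <- if (any(zone <= 1L)) rs$t[match(TRUE, zone <= 1L)] else NA_real_

  if (effective) {
    counted <- events$t_start < t_platform
    n <- sum(counted)
    direct <- n == 0L || t_arrival <= min(events$t_start[counted])
    directionality <- if (direct) "direct" else "indirect"
    category <- precision_band(n, direct)
  } else {
    counted <- rep(TRUE, nrow(events))
    n <- nrow(events)
    directionality <- "not-applicable"
    frac_z4 <- mean(zone == 4L)
    if (frac_z4 >= 1 - params$thigmo_tol) {
      category <- "J"
    } else if (octants_localized(unique(oct))) {
      category <- "H"
    } else {
      category <- "I"
    }
  }
  events$counted <- counted

  structure(
    list(
      category = factor(category, levels = LETTERS[1:10]),
      effective = effective,
      directionality = directionality,
      n_changes = n,
      n_curves = sum(events$kind == "curve" & counted),
      n_nonsense = sum(events$kind == "nonsense" & counted),
      n_peripheral = sum(events$kind == "peripheral" & counted),
      events = events,
      t_platform = t_platform,
      t_arrival = t_arrival,
      meta = track_meta(track)
    ),
    class = "ssa_label"
  )
}

# Map a change count onto the precision bands.
precision_band <- function(n, direct) {
  if (direct) {
    if (n == 0L) "A" else if (n <= 3L) "B" else if (n <= 6L) "C" else "D"
  } else {
    if (n <= 3L) "E" else if (n <= 6L) "F" else "G"
  }
}

# TRUE when the occupied octant set has <= 3 members forming one contiguous
# arc (with wraparound).
octants_localized <- function(occ) {
  occ <- sort(unique(as.integer(occ)))
  k <- length(occ)
  if (k > 3L) return(FALSE)
  if (k <= 1L) return(TRUE)
  breaks <- sum(!(((occ + 1L) %% 8L) %in% occ))
  breaks == 1L
}

#' @export
print.ssa_label <- function(x, ...) {
  cat(sprintf(
    "<ssa_label> category %s (%s, %s), %d trajectory change(s): %d curve, %d nonsense, %d peripheral\n",
    as.character(x$category),
    if (x$effective) "effective" else "ineffective",
    x$directionality, x$n_changes, x$n_curves, x$n_nonsense, x$n_peripheral
  ))
  if (x$effective) cat(sprintf("  platform reached at %.1f s\n", x$t_platform))
  invisible(x)
}

#' Broom-style accessors for classification results
#'
#' `tidy()` returns the event-level audit table (one row per detected
#' trajectory change); `glance()` returns the one-row trial summary used to
#' build label tables.
#'
#' @param x An `ssa_label` from [ssa_classify()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ssa_label
#' @export
tidy.ssa_label <- function(x, ...) {
  m <- x$meta
  dplyr::bind_cols(
    tibble::tibble(
      animal_id = m$animal_id %||% NA_character_,
      day = m$day %||% NA_integer_,
      trial_index = m$trial_index %||% NA_integer_
    )[rep(1, nrow(x$events)), ],
    x$events
  )
}

#' @rdname tidy.ssa_label
#' @method glance ssa_label
#' @export
glance.ssa_label <- function(x, ...) {
  m <- x$meta
  tibble::tibble(
    animal_id = m$animal_id %||% NA_character_,
    group = m$group %||% NA_character_,
    day = m$day %||% NA_integer_,
    trial_index = m$trial_index %||% NA_integer_,
    trial_type = m$trial_type %||% NA_character_,
    category = as.character(x$category),
    effective = x$effective,
    directionality = x$directionality,
    n_changes = x$n_changes,
    n_curves = x$n_curves,
    n_nonsense = x$n_nonsense,
    n_peripheral = x$n_peripheral,
    t_platform = x$t_platform
  )
}

#' Classify a set of trials
#'
#' Maps [ssa_classify()] over a trial table (tibble with a `track`
#' list-column, as returned by [generate_cohort()] or [read_tracks()]).
#'
#' @param trials A tibble with a list-column `track`.
#' @param cfg A [pool_config()].
#' @param params A [classifier_params()].
#' @return A tibble with one row per trial (the [glance.ssa_label()]
#'   columns) and a list-column `label` holding the full `ssa_label`
#'   objects.
#' @export
classify_trials <- function(trials, cfg, params = classifier_params()) {
  stopifnot("track" %in% names(trials))
  labels <- purrr::map(trials$track, ssa_classify, cfg = cfg, params = params)
  out <- purrr::map_dfr(labels, glance)
  out$label <- labels
  out
}

#' Strategy parameters from category labels
#'
#' Expands A-J category labels into the three classification parameters
#' (useful for parameter-wise inter-rater agreement) and the pooled class
#' used in group comparisons: direct (A-D), indirect (E-G), non-effective
#' (H-J).
#'
#' @param category A character or factor vector of categories A-J.
#' @return A tibble: `category`, `pooled`, `effective`, `directionality`,
#'   `precision_band` (0 = no changes, 1 = 1-3, 2 = 4-6, 3 = >= 7; `NA` for
#'   ineffective strategies).
#' @export
strategy_parameters <- function(category) {
  category <- as.character(category)
  bad <- !category %in% LETTERS[1:10]
  if (any(bad)) stop("unknown categories: ", paste(unique(category[bad]), collapse = ", "),
                     call. = FALSE)
  pooled <- dplyr::case_when(
    category %in% c("A", "B", "C", "D") ~ "direct",
    category %in% c("E", "F", "G") ~ "indirect",
    TRUE ~ "non_effective"
  )
  band <- dplyr::case_when(
    category == "A" ~ 0L,
    category %in% c("B", "E") ~ 1L,
    category %in% c("C", "F") ~ 2L,
    category %in% c("D", "G") ~ 3L,
    TRUE ~ NA_integer_
  )
  tibble::tibble(
    category = category,
    pooled = factor(pooled, levels = c("direct", "indirect", "non_effective")),
    effective = pooled != "non_effective",
    directionality = dplyr::case_when(
      pooled == "direct" ~ "direct",
      pooled == "indirect" ~ "indirect",
      TRUE ~ "not-applicable"
    ),
    precision_band = band
  )
}
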