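#' Traditional per-trial water maze measures
#'
#' Computes the classical Morris water maze measures for one trial:
#' \describe{
#'   \item{platform_latency}{Time (s) of the first sample inside the
#'     platform zone (zone 0). Trials that never reach the platform are
#'     censored at the trial duration.}
#'   \item{platform_distance}{Swim path length (cm) from the start to that
#'     first zone-0 sample (full path length when censored).}
#'   \item{mean_speed}{Total path length / elapsed time (cm/s), on the
#'     cleaned resampled (unsmoothed) track.}
#'   \item{quadrant_time_pct}{Percentage of trial time whose sample-interval
#'     midpoint lies in the correct quadrant (the one containing the
#'     platform).}
#'   \item{platform_crossings}{Number of entry transitions into zone 0;
#'     starting inside zone 0 counts as one crossing.}
#'   \item{found_platform}{Whether zone 0 was ever reached.}
#' }
#'
#' A configurable `min_dwell` (s) is available for labs that require the
#' animal to remain on the platform before counting an arrival; the default
#' 0 counts the first entry.
#'
#' @param track A raw [swim_track()].
#' @param cfg A [pool_config()].
#' @param dt Resampling interval (s).
#' @param min_dwell Minimum continuous time (s) in zone 0 for an entry to
#'   count as reaching the platform.
#' @return A one-row tibble with the metrics plus the trial metadata columns
#'   `animal_id`, `group`, `day`, `trial_index`, `trial_type`.
#' @examples
#' cfg <- pool_config()
#' tr <- generate_archetype(archetype_spec("A", noise_sd = 0, seed = 1), cfg)$track
#' trial_metrics(tr, cfg)
#' @export
trial_metrics <- function(track, cfg, dt = 0.1, min_dwell = 0) {
  meta <- track_meta(track)
  rs <- resample_track(track, dt = dt)
  zone <- zone_of(rs$x, rs$y, cfg)
  n <- nrow(rs)
  seg <- sqrt(diff(rs$x)^2 + diff(rs$y)^2)
  total_len <- sum(seg)
  elapsed <- rs$t[n] - rs$t[1]
  if (elapsed <= 0) stop("zero elapsed time", call. = FALSE)

  hit <- first_platform_entry(rs$t, zone, min_dwell)
  found <- !is.na(hit)
  duration <- meta$trial_duration %||% 90
  if (found) {
    latency <- rs$t[hit]
    distance <- if (hit == 1L) 0 else sum(seg[seq_len(hit - 1L)])
  } else {
    latency <- duration
    distance <- total_len
  }

  # fraction of interval time whose midpoint sits in the correct quadrant
  mx <- (rs$x[-1] + rs$x[-n]) / 2
  my <- (rs$y[-1] + rs$y[-n]) / 2
  dtv <- diff(rs$t)
  in_cq <- quadrant_of(mx, my, cfg) == correct_quadrant(cfg)
  quad_pct <- 100 * sum(dtv[in_cq]) / sum(dtv)

  entries <- zone_entries(zone)

  tibble::tibble(
    animal_id = meta$animal_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    day = meta$day %||% NA_integer_,
    trial_index = meta$trial_index %||% NA_integer_,
    trial_type = meta$trial_type %||% NA_character_,
    platform_latency = latency,
    platform_distance = distance,
    mean_speed = total_len / elapsed,
    quadrant_time_pct = quad_pct,
    platform_crossings = entries,
    found_platform = found
  )
}

# Index of the first zone-0 sample that begins a dwell of >= min_dwell
# seconds, or NA when the platform is never (sufficiently) reached.
first_platform_entry <- function(t, zone, min_dwell = 0) {
  r <- rle(zone == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    dwell <- t[ends[k]] - t[starts[k]]
    if (dwell >= min_dwell) return(starts[k])
  }
  NA_integer_
}

# Number of entry transitions into zone 0 (start inside counts as one).
zone_entries <- function(zone) {
  inside <- zone == 0L
  sum(inside & !c(FALSE, inside[-length(inside)]))
}

#' Metrics for a set of trials
#'
#' Maps [trial_metrics()] over a trial table as produced by
#' [generate_cohort()] or [read_tracks()] (a tibble with a `track`
#' list-column).
#'
#' @param trials A tibble with a list-column `track` of [swim_track()]s.
#' @param cfg A [pool_config()].
#' @param ... Passed to [trial_metrics()].
#' @return A tibble, one row per trial.
#' @export
trials_metrics <- function(trials, cfg, ...) {
  stopifnot("track" %in% names(trials))
  purrr::map_dfr(trials$track, trial_metrics, cfg = cfg, ...)
}
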