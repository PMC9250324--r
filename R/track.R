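#' Swim track objects
#'
#' A swim track is a tibble with columns `t` (seconds), `x`, and `y`
#' (pool-centred cm), one row per tracked sample, carrying trial metadata as
#' attributes: `animal_id`, `group` (`"young"`/`"aged"`), `day`,
#' `trial_index`, `trial_type` (`"pretraining"`, `"acquisition"`, `"probe"`),
#' `trial_duration` (s), and `start_octant`.
#'
#' @param data A data frame with numeric columns `t`, `x`, `y`.
#' @param animal_id Animal identifier.
#' @param group Cohort label, typically `"young"` or `"aged"`.
#' @param day Protocol day (integer >= 0).
#' @param trial_index Trial number within the day.
#' @param trial_type One of `"pretraining"`, `"acquisition"`, `"probe"`.
#' @param trial_duration Trial length in seconds (default 90).
#' @param start_octant Octant index (0-7) of the release point, if known.
#' @param cfg Optional [pool_config()]; when supplied, points are checked to
#'   lie inside the pool (plus wall tolerance).
#'
#' @return A tibble of class `swim_track`.
#' @examples
#' tr <- swim_track(data.frame(t = 0:3, x = c(0, 10, 20, 30), y = 0))
#' track_meta(tr)$trial_duration
#' @export
swim_track <- function(data,
                       animal_id = NA_character_,
                       group = NA_character_,
                       day = NA_integer_,
                       trial_index = NA_integer_,
                       trial_type = "acquisition",
                       trial_duration = 90,
                       start_octant = NA_integer_,
                       cfg = NULL) {
  stopifnot(is.data.frame(data), all(c("t", "x", "y") %in% names(data)))
  out <- tibble::as_tibble(data[c("t", "x", "y")])
  if (nrow(out) < 2L) stop("a swim track needs at least 2 points", call. = FALSE)
  if (!all(vapply(out, is.numeric, logical(1)))) {
    stop("t, x, y must be numeric", call. = FALSE)
  }
  if (anyNA(out) || !all(is.finite(as.matrix(out)))) {
    stop("swim track contains non-finite values; clean before constructing", call. = FALSE)
  }
  if (any(diff(out$t) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (out$t[1] < 0) stop("time must be non-negative", call. = FALSE)
  if (out$t[nrow(out)] > trial_duration + 1e-6) {
    stop(sprintf("track extends to %.2f s, beyond the %.0f s trial duration",
                 out$t[nrow(out)], trial_duration), call. = FALSE)
  }
  if (!is.null(cfg)) check_in_pool(out$x, out$y, cfg)
  meta <- list(
    animal_id = animal_id, group = group, day = day,
    trial_index = trial_index, trial_type = trial_type,
    trial_duration = trial_duration, start_octant = start_octant
  )
  new_swim_track(out, meta)
}

new_swim_track <- function(data, meta) {
  structure(
    tibble::as_tibble(data),
    meta = meta,
    class = c("swim_track", class(tibble::tibble()))
  )
}

#' @rdname swim_track
#' @param track A `swim_track`.
#' @return `track_meta()`: the metadata as a named list.
#' @export
track_meta <- function(track) {
  attr(track, "meta") %||% list(trial_duration = 90)
}

#' @export
print.swim_track <- function(x, ...) {
  m <- track_meta(x)
  cat(sprintf(
    "<swim_track> %d samples over %.1f s (animal %s, %s, day %s, trial %s, %s)\n",
    nrow(x), x$t[nrow(x)] - x$t[1],
    m$animal_id, m$group, m$day, m$trial_index, m$trial_type
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
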