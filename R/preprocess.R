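#' Resample a track onto a uniform time grid
#'
#' Linear interpolation of `x` and `y` onto `seq(t0, t_last, by = dt)`; the
#' final sample is appended when the span is not a multiple of `dt`, so both
#' endpoints are always preserved. Resampling at the same `dt` is idempotent
#' for already-uniform tracks.
#'
#' @param track A [swim_track()].
#' @param dt Target sampling interval (s), > 0.
#' @return A resampled [swim_track()] with the same metadata.
#' @export
resample_track <- function(track, dt = 0.1) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  t <- track$t
  span <- t[length(t)] - t[1]
  if (dt > span) stop("dt is larger than the trajectory time span", call. = FALSE)
  grid <- seq(t[1], t[length(t)], by = dt)
  if (t[length(t)] - grid[length(grid)] > 1e-9) grid <- c(grid, t[length(t)])
  xi <- stats::approx(t, track$x, xout = grid)$y
  yi <- stats::approx(t, track$y, xout = grid)$y
  out <- tibble::tibble(t = grid, x = xi, y = yi)
  new_swim_track(out, track_meta(track))
}

#' Smooth a track with a centred moving average
#'
#' Averages `x` and `y` over a centred window, symmetrically shrunk near the
#' endpoints (so a uniformly sampled straight-line track is reproduced
#' exactly, and endpoints are never extrapolated). `window = 1` is the
#' identity. Time stamps are unchanged.
#'
#' @param track A [swim_track()], normally already resampled.
#' @param window Odd window length in samples, `1 <= window <= nrow(track)`.
#' @return A smoothed [swim_track()].
#' @export
smooth_track <- function(track, window = 5) {
  n <- nrow(track)
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer", call. = FALSE)
  if (window > n) stop("window exceeds the number of samples", call. = FALSE)
  if (window == 1) return(track)
  half <- (window - 1L) / 2L
  run_mean <- function(v) {
    cs <- c(0, cumsum(v))
    i <- seq_len(n)
    h <- pmin(half, i - 1L, n - i)
    (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out <- tibble::tibble(t = track$t, x = run_mean(track$x), y = run_mean(track$y))
  new_swim_track(out, track_meta(track))
}

#' Heading series of a track
#'
#' Converts a (resampled, usually smoothed) track into per-step compass
#' bearings and signed turn angles, the substrate for trajectory-change
#' detection. Consecutive samples closer than `min_step` cm are merged
#' first, so sub-centimetre tracking jitter cannot manufacture large turn
#' angles. Turns are wrapped to `(-180, 180]`, positive clockwise.
#'
#' @param track A [swim_track()].
#' @param min_step Minimum step displacement (cm) between retained vertices.
#' @return A `heading_series`: a list with
#'   \describe{
#'     \item{steps}{tibble of effective steps: `t0`, `t1`, `x0`, `y0`, `x1`,
#'       `y1`, `bearing` (deg), `length` (cm).}
#'     \item{turns}{tibble of vertices between consecutive steps: `t` (time
#'       at the vertex), `x`, `y`, and signed `turn` (deg).}
#'   }
#'   With fewer than 3 effective vertices the turn table is empty (no turns
#'   measurable).
#' @export
track_headings <- function(track, min_step = 1) {
  n <- nrow(track)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    d <- sqrt((track$x[i] - track$x[last])^2 + (track$y[i] - track$y[last])^2)
    if (d >= min_step) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep[n] <- TRUE # always retain the endpoint
  px <- track$x[keep]; py <- track$y[keep]; pt <- track$t[keep]
  m <- length(px)
  if (m >= 2 && sqrt((px[m] - px[m - 1])^2 + (py[m] - py[m - 1])^2) < 1e-12) {
    px <- px[-m]; py <- py[-m]; pt <- pt[-m]; m <- m - 1L
  }
  if (m < 2) {
    steps <- tibble::tibble(t0 = numeric(), t1 = numeric(), x0 = numeric(),
                            y0 = numeric(), x1 = numeric(), y1 = numeric(),
                            bearing = numeric(), length = numeric())
  } else {
    steps <- tibble::tibble(
      t0 = pt[-m], t1 = pt[-1],
      x0 = px[-m], y0 = py[-m], x1 = px[-1], y1 = py[-1],
      bearing = bearing_of(diff(px), diff(py)),
      length = sqrt(diff(px)^2 + diff(py)^2)
    )
  }
  if (m < 3) {
    turns <- tibble::tibble(t = numeric(), x = numeric(), y = numeric(),
                            turn = numeric())
  } else {
    turns <- tibble::tibble(
      t = pt[2:(m - 1)],
      x = px[2:(m - 1)],
      y = py[2:(m - 1)],
      turn = wrap_turn(diff(steps$bearing))
    )
  }
  structure(list(steps = steps, turns = turns), class = "heading_series")
}

#' @export
print.heading_series <- function(x, ...) {
  cat(sprintf("<heading_series> %d steps, %d turns, total |turn| = %.1f deg\n",
              nrow(x$steps), nrow(x$turns), sum(abs(x$turns$turn))))
  invisible(x)
}

#' Standard preprocessing pipeline
#'
#' Resamples the raw track at `dt`, smooths a copy for angle measurement,
#' and extracts the heading series. Zone and octant sequences are taken from
#' the resampled (unsmoothed) track, since smoothing slightly shortens and
#' displaces the path; angles are taken from the smoothed track.
#'
#' @param track A raw [swim_track()].
#' @param params A [classifier_params()] (supplies `dt`, `smooth_window`,
#'   `min_step`).
#' @return A list: `resampled` (swim_track), `smoothed` (swim_track),
#'   `headings` (heading_series).
#' @export
preprocess_track <- function(track, params = classifier_params()) {
  rs <- resample_track(track, dt = params$dt)
  sm <- smooth_track(rs, window = min(params$smooth_window, nrow(rs) - (1 - nrow(rs) %% 2)))
  list(resampled = rs, smoothed = sm,
       headings = track_headings(sm, min_step = params$min_step))
}
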