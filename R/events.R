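#' Classifier parameters
#'
#' All thresholds of the search-strategy classifier in one place. The curve
#' threshold (> 90 degrees, strict), the peripheral octant limits (more than
#' 3 contiguous octants in zone 3, more than 1 in zone 4), and the precision
#' bands are the published decision-tree constants; the remaining values
#' operationalise what a human rater judges visually (what counts as a
#' zigzag or spiral, how much jitter to ignore) and are deliberately
#' tunable.
#'
#' @param curve_angle Cumulative turn (deg) a same-direction run must
#'   strictly exceed to count as a curved-movement change.
#' @param zig_angle Minimum per-swing magnitude (deg) for zigzag swings.
#' @param zig_count Minimum number of consecutive alternating swings.
#' @param zig_max_gap Maximum time (s) between consecutive zigzag swings.
#' @param spiral_total Cumulative same-direction turn (deg) beyond which a
#'   run counts as a spiral (nonsense movement) rather than a curve.
#' @param z3_octants A zone-3 episode is peripheral seeking when it
#'   traverses more than this many octants.
#' @param z4_octants As above for zone-4 episodes.
#' @param turn_tol Per-step turns at or below this magnitude (deg) are
#'   treated as straight swimming (tracking jitter / gentle drift).
#' @param opp_tol An opposite-signed turn must exceed this magnitude (deg)
#'   to terminate a same-direction run (hysteresis against jitter).
#' @param straight_break Straight swimming lasting at least this long (s)
#'   ends the current run.
#' @param min_turn_rate Minimum peak turning rate (deg/s, best
#'   `straight_break`-long window within the run) for a run to qualify as
#'   a trajectory change. Deliberate arcs and swings concentrate their
#'   turning; runs opened by a jitter spike and then fed by slow
#'   sub-threshold drift never reach this rate, and are discarded.
#' @param thigmo_tol Fraction of samples allowed outside zone 4 while still
#'   calling a trial thigmotaxis (J).
#' @param dt Resampling interval (s) of the preprocessing pipeline.
#' @param smooth_window Moving-average window (samples) for angle
#'   measurement.
#' @param min_step Minimum vertex displacement (cm) in [track_headings()].
#' @return A `classifier_params` object (named list).
#' @export
classifier_params <- function(curve_angle = 90,
                              zig_angle = 45,
                              zig_count = 3,
                              zig_max_gap = 1,
                              spiral_total = 360,
                              z3_octants = 3,
                              z4_octants = 1,
                              turn_tol = 10,
                              opp_tol = 30,
                              straight_break = 0.5,
                              min_turn_rate = 125,
                              thigmo_tol = 0.05,
                              dt = 0.1,
                              smooth_window = 7,
                              min_step = 1) {
  p <- as.list(environment())
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, logical(1))
  if (any(bad)) stop("classifier_params must be single non-negative numbers: ",
                     paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "classifier_params")
}

#' Segment a turn series into same-direction runs
#'
#' The elementary grouping behind curve, spiral, and zigzag detection. A run
#' is a maximal stretch of turning in one rotational direction: it opens at
#' a significant turn (|turn| > `turn_tol`, back-extended over the
#' same-signed sub-threshold ramp that smoothing spreads ahead of a sharp
#' turn), accumulates the signed turn, and closes either when straight
#' swimming persists for `straight_break` seconds or when the cumulative
#' turn retreats more than `opp_tol` degrees from its running extreme (a
#' drawdown, i.e. the rotation direction has genuinely flipped). The run
#' ends at its cumulative extreme and its magnitude is the net heading
#' change committed there; the retreating turns seed the next run. The
#' drawdown rule makes segmentation insensitive to how resampling and
#' smoothing spread a sharp corner across samples.
#'
#' @param h A `heading_series` from [track_headings()].
#' @param params A [classifier_params()].
#' @return A tibble with one row per run: `sign` (+1 clockwise, -1
#'   counter-clockwise), `cum` (signed cumulative turn, deg), `i_start`,
#'   `i_end` (turn indices), `t_start`, `t_end` (s), and `peak_rate`
#'   (deg/s over the fastest `straight_break`-long window).
#' @export
segment_runs <- function(h, params = classifier_params()) {
  tau <- h$turns$turn
  tt <- h$turns$t
  n <- length(tau)
  empty <- tibble::tibble(sign = numeric(), cum = numeric(),
                          i_start = integer(), i_end = integer(),
                          t_start = numeric(), t_end = numeric(),
                          peak_rate = numeric())
  if (n == 0L) return(empty)

  runs <- list()
  i <- 1L
  while (i <= n) {
    if (abs(tau[i]) <= params$turn_tol) {
      i <- i + 1L
      next
    }
    s <- sign(tau[i])
    # back-extend over the same-signed sub-threshold ramp that smoothing
    # spreads out ahead of a sharp turn
    start <- i
    lo <- if (length(runs)) runs[[length(runs)]]["i_end"] + 1L else 1L
    back <- 0L
    max_ext <- 5L
    while (start > lo && back < max_ext &&
           tau[start - 1L] * s > 0 && abs(tau[start - 1L]) <= params$turn_tol) {
      start <- start - 1L
      back <- back + 1L
    }
    cum <- sum(tau[start:i])
    peak <- s * cum
    i_peak <- i
    straight_since <- NA_real_
    j <- i + 1L
    while (j <= n) {
      cum <- cum + tau[j]
      if (s * cum > peak) {
        peak <- s * cum
        i_peak <- j
      }
      if (peak - s * cum > params$opp_tol) break # drawdown: direction flipped
      if (abs(tau[j]) <= params$turn_tol) {
        if (is.na(straight_since)) straight_since <- tt[j]
        if (tt[j] - straight_since >= params$straight_break) break
      } else {
        straight_since <- NA_real_
      }
      j <- j + 1L
    }
    # peak turning rate: largest turn committed within any window of
    # `straight_break` seconds inside the run
    w <- params$straight_break
    best <- 0
    jj <- start
    for (ii in start:i_peak) {
      if (jj < ii) jj <- ii
      while (jj < i_peak && tt[jj + 1L] - tt[ii] <= w) jj <- jj + 1L
      best <- max(best, abs(sum(tau[ii:jj])))
    }
    runs[[length(runs) + 1L]] <- c(sign = s, cum = s * peak,
                                   i_start = start, i_end = i_peak,
                                   peak_rate = best / w)
    i <- i_peak + 1L
  }
  if (length(runs) == 0L) return(empty)
  out <- as.data.frame(do.call(rbind, runs))
  tibble::tibble(
    sign = out$sign, cum = out$cum,
    i_start = as.integer(out$i_start), i_end = as.integer(out$i_end),
    t_start = tt[out$i_start], t_end = tt[out$i_end],
    peak_rate = out$peak_rate
  )
}

new_events <- function(kind = character(), subtype = character(),
                       t_start = numeric(), t_end = numeric(),
                       i_start = integer(), i_end = integer(),
                       magnitude = numeric()) {
  tibble::tibble(kind = kind, subtype = subtype,
                 t_start = t_start, t_end = t_end,
                 i_start = i_start, i_end = i_end,
                 magnitude = magnitude)
}

#' Detect curved-movement trajectory changes
#'
#' A curve change is a maximal same-direction run (see [segment_runs()])
#' whose cumulative turn strictly exceeds `curve_angle` (more than 90
#' degrees of angulation under the defaults). Runs that also exceed the
#' spiral threshold are reported here too; [merge_events()] subsumes them
#' under the nonsense event that [detect_nonsense()] reports.
#'
#' @inheritParams segment_runs
#' @return An event tibble: `kind`, `subtype`, `t_start`, `t_end`,
#'   `i_start`, `i_end`, `magnitude` (signed cumulative turn, deg).
#' @export
detect_curves <- function(h, params = classifier_params()) {
  runs <- segment_runs(h, params)
  # strict threshold, guarded against floating accumulation: a nominal
  # 90-degree arc must not register
  hit <- abs(runs$cum) > params$curve_angle + 1e-9 &
    runs$peak_rate >= params$min_turn_rate
  new_events(
    kind = rep("curve", sum(hit)),
    subtype = rep("curve", sum(hit)),
    t_start = runs$t_start[hit], t_end = runs$t_end[hit],
    i_start = runs$i_start[hit], i_end = runs$i_end[hit],
    magnitude = runs$cum[hit]
  )
}

#' Detect nonsense movements (zigzags and spirals)
#'
#' Spirals are same-direction runs whose cumulative turn exceeds
#' `spiral_total` (a full loop and more). Zigzags are chains of at least
#' `zig_count` consecutive runs of alternating direction, each of magnitude
#' at least `zig_angle`, with at most `zig_max_gap` seconds between
#' consecutive swings. Each maximal chain or qualifying run yields one
#' event.
#'
#' @inheritParams segment_runs
#' @return An event tibble (see [detect_curves()]); `subtype` is
#'   `"zigzag"` or `"spiral"`, `magnitude` the total absolute turn (deg).
#' @export
detect_nonsense <- function(h, params = classifier_params()) {
  runs <- segment_runs(h, params)
  ev <- new_events()
  if (nrow(runs) == 0L) return(ev)

  spiral <- abs(runs$cum) > params$spiral_total + 1e-9 &
    runs$peak_rate >= params$min_turn_rate
  if (any(spiral)) {
    ev <- dplyr::bind_rows(ev, new_events(
      kind = rep("nonsense", sum(spiral)),
      subtype = rep("spiral", sum(spiral)),
      t_start = runs$t_start[spiral], t_end = runs$t_end[spiral],
      i_start = runs$i_start[spiral], i_end = runs$i_end[spiral],
      magnitude = abs(runs$cum[spiral])
    ))
  }

  # zigzag swings are not rate-gated: the chain structure (three or more
  # alternating swings within zig_max_gap) is itself a strong filter, and
  # a legitimate 45-60 degree swing can be too small to clear the rate bar
  eligible <- abs(runs$cum) >= params$zig_angle - 1e-9 & !spiral
  k <- nrow(runs)
  chain_start <- NA_integer_
  chains <- list()
  flush <- function(end_idx) {
    if (!is.na(chain_start) && end_idx - chain_start + 1L >= params$zig_count) {
      chains[[length(chains) + 1L]] <<- c(chain_start, end_idx)
    }
    chain_start <<- NA_integer_
  }
  for (i in seq_len(k)) {
    if (!eligible[i]) {
      flush(i - 1L)
      next
    }
    if (is.na(chain_start)) {
      chain_start <- i
    } else {
      linked <- eligible[i - 1L] &&
        runs$sign[i] != runs$sign[i - 1L] &&
        (runs$t_start[i] - runs$t_end[i - 1L]) <= params$zig_max_gap
      if (!linked) {
        flush(i - 1L)
        chain_start <- i
      }
    }
  }
  flush(k)
  for (ch in chains) {
    idx <- ch[1]:ch[2]
    ev <- dplyr::bind_rows(ev, new_events(
      kind = "nonsense", subtype = "zigzag",
      t_start = runs$t_start[ch[1]], t_end = runs$t_end[ch[2]],
      i_start = runs$i_start[ch[1]], i_end = runs$i_end[ch[2]],
      magnitude = sum(abs(runs$cum[idx]))
    ))
  }
  dplyr::arrange(ev, .data$t_start)
}

#' Detect peripheral-seeking trajectory changes
#'
#' Works on the per-sample (zone, octant) sequence of the resampled track.
#' A peripheral event is a maximal episode during which the animal stays in
#' zone 3 while traversing more than `z3_octants` distinct octants, or
#' stays in zone 4 while traversing more than `z4_octants` distinct
#' octants; an episode confined to its starting octant traverses one
#' octant. (Distinct octants, not boundary crossings: jittering back and
#' forth across a single boundary is not peripheral seeking.)
#'
#' @param track A resampled [swim_track()] (raw positions, not smoothed).
#' @param cfg A [pool_config()].
#' @param params A [classifier_params()].
#' @return An event tibble (see [detect_curves()]); `magnitude` is the
#'   octant count, `subtype` `"zone3"` or `"zone4"`.
#' @export
detect_peripheral <- function(track, cfg, params = classifier_params()) {
  zone <- zone_of(track$x, track$y, cfg)
  oct <- octant_of(track$x, track$y, cfg)
  ev <- new_events()
  for (z in c(3L, 4L)) {
    limit <- if (z == 3L) params$z3_octants else params$z4_octants
    r <- rle(zone == z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      idx <- starts[k]:ends[k]
      n_oct <- length(unique(oct[idx]))
      if (n_oct > limit) {
        ev <- dplyr::bind_rows(ev, new_events(
          kind = "peripheral", subtype = paste0("zone", z),
          t_start = track$t[starts[k]], t_end = track$t[ends[k]],
          i_start = starts[k], i_end = ends[k],
          magnitude = n_oct
        ))
      }
    }
  }
  dplyr::arrange(ev, .data$t_start)
}

#' Merge detected events into one trajectory-change sequence
#'
#' Combines curve, nonsense, and peripheral events into the trial's ordered
#' change list. Curve events overlapping a nonsense event in time are
#' subsumed by it (a spiral is the extreme of its own curve; a zigzag's
#' sharp swings are not additionally counted as curves). Peripheral events
#' are kept separately: they live on the zone/octant substrate, not the
#' heading series.
#'
#' @param curves,nonsense,peripheral Event tibbles from the detectors.
#' @return The combined event tibble, sorted by `t_start`.
#' @export
merge_events <- function(curves, nonsense, peripheral = NULL) {
  if (nrow(curves) > 0 && nrow(nonsense) > 0) {
    overlapped <- vapply(seq_len(nrow(curves)), function(i) {
      any(curves$t_start[i] <= nonsense$t_end &
            curves$t_end[i] >= nonsense$t_start)
    }, logical(1))
    curves <- curves[!overlapped, ]
  }
  out <- dplyr::bind_rows(curves, nonsense, peripheral)
  dplyr::arrange(out, .data$t_start)
}
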