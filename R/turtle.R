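# Internal turtle-graphics path builder for the synthetic generator.
#
# A path is grown step by step at a fixed generation rate. Two regimes are
# kept strictly apart so that ground truth is defined by construction:
#  - "steering": per-step turns capped at `steer_cap` deg/s, chosen well
#    below the classifier's per-step significance threshold, so navigation
#    (approaches, corrections, obstacle avoidance, wandering) can never
#    register as a trajectory change;
#  - "motifs": sharp arcs/corners at `arc_rate` deg/s and above, which are
#    the deliberately inserted trajectory changes.

TT_DT <- 0.05        # generation sampling interval (s)
TT_STEER_CAP <- 70   # deg/s; ~7 deg per analysis step at dt = 0.1
TT_ARC_RATE <- 200   # deg/s for curve/spiral motifs; ~20 deg per analysis step

tt_new <- function(x0, y0, heading, speed, duration, dt = TT_DT) {
  cap <- as.integer(ceiling(duration / dt)) + 2L
  env <- new.env(parent = emptyenv())
  env$x <- numeric(cap); env$y <- numeric(cap)
  env$x[1] <- x0; env$y[1] <- y0
  env$n <- 1L
  env$cap <- cap
  env$heading <- heading %% 360
  env$v <- speed
  env$dt <- dt
  env$duration <- duration
  env
}

tt_time <- function(T) (T$n - 1L) * T$dt

tt_pos <- function(T) c(T$x[T$n], T$y[T$n])

tt_step <- function(T, turn = 0) {
  if (T$n >= T$cap) {
    stop(sprintf(
      "infeasible archetype: construction does not fit in the %.0f s trial",
      T$duration), call. = FALSE)
  }
  T$heading <- (T$heading + turn) %% 360
  rad <- T$heading * pi / 180
  i <- T$n + 1L
  T$x[i] <- T$x[T$n] + T$v * T$dt * sin(rad)
  T$y[i] <- T$y[T$n] + T$v * T$dt * cos(rad)
  T$n <- i
  invisible(T)
}

tt_straight <- function(T, dur) {
  for (i in seq_len(max(1L, round(dur / T$dt)))) tt_step(T, 0)
  invisible(T)
}

tt_arc <- function(T, angle, rate = TT_ARC_RATE) {
  steps <- max(1L, ceiling(abs(angle) / (rate * T$dt)))
  per <- angle / steps
  for (i in seq_len(steps)) tt_step(T, per)
  invisible(T)
}

# Align the heading to `target` using sub-threshold steering turns only.
tt_steer_heading <- function(T, target, cap = TT_STEER_CAP) {
  max_turn <- cap * T$dt
  repeat {
    d <- wrap_turn(target - T$heading)
    if (abs(d) <= max_turn) {
      if (abs(d) > 1e-9) tt_step(T, d)
      break
    }
    tt_step(T, sign(d) * max_turn)
  }
  invisible(T)
}

# Desired bearing with platform avoidance, wall repulsion, and optional
# centre repulsion (used by confined searches whose octant identity would
# destabilise near the pool centre) folded in.
tt_desired <- function(T, target, cfg, avoid_platform, wall_limit, min_r = 0) {
  p <- tt_pos(T)
  desired <- bearing_of(target[1] - p[1], target[2] - p[2])
  r <- sqrt(p[1]^2 + p[2]^2)
  if (r > wall_limit) desired <- bearing_of(-p[1], -p[2])
  if (min_r > 0 && r < min_r) desired <- bearing_of(p[1], p[2])
  if (avoid_platform) {
    pc <- platform_center(cfg)
    dp <- sqrt((p[1] - pc[["x"]])^2 + (p[2] - pc[["y"]])^2)
    if (dp < 22) desired <- bearing_of(p[1] - pc[["x"]], p[2] - pc[["y"]])
  }
  desired
}

# Steer toward a target point; stops within `stop_dist` cm or after
# `max_dur` seconds (an error by then means the construction went wrong).
# With `loose = TRUE` a target caught inside the minimum turning circle
# counts as reached (used for tour anchors, where exact arrival is
# irrelevant); otherwise the turtle moves off straight (only while safely
# away from the wall and not heading outward) before turning back.
tt_steer_to <- function(T, target, cfg, stop_dist = 3, cap = TT_STEER_CAP,
                        avoid_platform = TRUE, wall_limit = 78,
                        max_dur = 60, loose = FALSE) {
  max_turn <- cap * T$dt
  r_turn <- T$v * 180 / (pi * cap) # minimum turning radius at this cap
  steps <- 0L
  limit <- as.integer(max_dur / T$dt)
  repeat {
    p <- tt_pos(T)
    dist <- sqrt((p[1] - target[1])^2 + (p[2] - target[2])^2)
    if (dist <= stop_dist) break
    if (steps >= limit) {
      stop("synthetic path failed to reach its waypoint; infeasible construction",
           call. = FALSE)
    }
    desired <- tt_desired(T, target, cfg, avoid_platform, wall_limit)
    d <- wrap_turn(desired - T$heading)
    orbiting <- dist < 2.2 * r_turn && abs(d) > 60
    if (orbiting && loose) break
    r <- sqrt(p[1]^2 + p[2]^2)
    outward <- abs(wrap_turn(T$heading - bearing_of(p[1], p[2]))) < 90
    if (orbiting && (r < 55 || !outward)) {
      # target inside the turning circle: move off before turning back,
      # otherwise the path orbits the waypoint forever
      tt_step(T, 0)
    } else {
      tt_step(T, sign(d) * min(abs(d), max_turn))
    }
    steps <- steps + 1L
  }
  invisible(T)
}

# Steer toward a target for a fixed duration, with avoidance fields on;
# never breaks early and never errors. Used to relocate before open-loop
# motifs: even if the turtle ends up orbiting the target, it orbits in the
# target's safe neighbourhood.
tt_steer_for <- function(T, target, dur, cfg, cap = TT_STEER_CAP,
                         avoid_platform = TRUE, wall_limit = 70) {
  max_turn <- cap * T$dt
  for (i in seq_len(max(1L, round(dur / T$dt)))) {
    desired <- tt_desired(T, target, cfg, avoid_platform, wall_limit)
    d <- wrap_turn(desired - T$heading)
    tt_step(T, sign(d) * min(abs(d), max_turn))
  }
  invisible(T)
}

# Wander among anchor points (cycled) until `until_time`, steering only.
tt_wander <- function(T, anchors, cfg, until_time, cap = TT_STEER_CAP,
                      avoid_platform = TRUE, wall_limit = 62, min_r = 0) {
  max_turn <- cap * T$dt
  r_turn <- T$v * 180 / (pi * cap)
  k <- 1L
  budget <- as.integer(12 / T$dt) # per-anchor step budget before moving on
  spent <- 0L
  skips <- 0L
  while (tt_time(T) < until_time - T$dt / 2) {
    target <- anchors[[k]]
    p <- tt_pos(T)
    dist <- sqrt((p[1] - target[1])^2 + (p[2] - target[2])^2)
    desired <- tt_desired(T, target, cfg, avoid_platform, wall_limit, min_r)
    d <- wrap_turn(desired - T$heading)
    orbiting <- dist < 2.2 * r_turn && abs(d) > 60
    if ((dist <= 4 || spent >= budget || orbiting) && skips <= length(anchors)) {
      k <- if (k == length(anchors)) 1L else k + 1L
      spent <- 0L
      skips <- skips + 1L
      next
    }
    skips <- 0L
    tt_step(T, sign(d) * min(abs(d), max_turn))
    spent <- spent + 1L
  }
  invisible(T)
}

# Follow the pool wall (clockwise) at `r_target` until `until_time` or until
# the position's polar angle has swept `sweep` degrees, whichever comes
# first. Turn rate at the wall is ~ v / r, far below significance.
tt_wall_follow <- function(T, r_target = 81, until_time = NULL, sweep = NULL,
                           until_r = NULL, tilt_max = 20, cap = TT_STEER_CAP) {
  max_turn <- cap * T$dt
  p0 <- tt_pos(T)
  swept <- 0
  prev_polar <- bearing_of(p0[1], p0[2])
  repeat {
    if (!is.null(until_time) && tt_time(T) >= until_time - T$dt / 2) break
    if (!is.null(sweep) && swept >= sweep) break
    if (!is.null(until_r)) {
      pr <- tt_pos(T)
      rr <- sqrt(pr[1]^2 + pr[2]^2)
      if ((r_target < rr && FALSE) || abs(rr - r_target) < 1 ||
          (r_target < 70 && rr <= until_r)) break
      if (r_target >= 70 && rr >= until_r) break
    }
    p <- tt_pos(T)
    polar <- bearing_of(p[1], p[2])
    r <- sqrt(p[1]^2 + p[2]^2)
    desired <- polar + 90 + max(-tilt_max, min(tilt_max, 4 * (r - r_target)))
    d <- wrap_turn(desired - T$heading)
    tt_step(T, sign(d) * min(abs(d), max_turn))
    new_polar <- bearing_of(T$x[T$n], T$y[T$n])
    swept <- swept + abs(wrap_turn(new_polar - prev_polar))
    prev_polar <- new_polar
  }
  invisible(T)
}

# Materialise the turtle as a swim_track (optionally with positional noise).
tt_track <- function(T, meta, noise_sd = 0, cfg = NULL) {
  idx <- seq_len(T$n)
  x <- T$x[idx]; y <- T$y[idx]
  t <- (idx - 1L) * T$dt
  keep <- t <= (meta$trial_duration %||% T$duration) + 1e-9
  x <- x[keep]; y <- y[keep]; t <- t[keep]
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
    if (!is.null(cfg)) {
      r <- sqrt(x^2 + y^2)
      lim <- pool_radius(cfg) + cfg$wall_tolerance - 0.2
      over <- r > lim
      if (any(over)) {
        scl <- lim / r[over]
        x[over] <- x[over] * scl
        y[over] <- y[over] * scl
      }
    }
  }
  new_swim_track(tibble::tibble(t = t, x = x, y = y), meta)
}
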