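# Fixture builders: analytic track constructions, independent of the
# package's own turtle-based synthetic generator.

make_track <- function(t, x, y, ...) {
  swim_track(data.frame(t = t, x = x, y = y), ...)
}

# Straight constant-speed segment between two points.
straight_track <- function(from, to, speed = 20, dt = 0.1, t0 = 0, ...) {
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len / (speed * dt)) + 1L)
  s <- seq(0, 1, length.out = n)
  make_track(t0 + s * len / speed,
             from[1] + s * (to[1] - from[1]),
             from[2] + s * (to[2] - from[2]), ...)
}

# Straight lead-in, circular arc of `angle` degrees (positive clockwise),
# straight lead-out; constant speed. Built from closed-form circle
# geometry, not the package turtle.
arc_track <- function(angle, speed = 25, turn_rate = 200, dt = 0.05,
                      lead = 3, tail = 3, start = c(-40, -40),
                      heading = 0, ...) {
  pts <- list()
  pos <- start
  h <- heading
  add <- function(p) pts[[length(pts) + 1L]] <<- p
  add(pos)
  step_dir <- function(h) c(sin(h * pi / 180), cos(h * pi / 180))
  for (i in seq_len(round(lead / dt))) {
    pos <- pos + speed * dt * step_dir(h)
    add(pos)
  }
  n_arc <- max(1L, round(abs(angle) / (turn_rate * dt)))
  per <- angle / n_arc
  for (i in seq_len(n_arc)) {
    h <- h + per
    pos <- pos + speed * dt * step_dir(h)
    add(pos)
  }
  for (i in seq_len(round(tail / dt))) {
    pos <- pos + speed * dt * step_dir(h)
    add(pos)
  }
  m <- do.call(rbind, pts)
  make_track(seq_len(nrow(m)) * dt, m[, 1], m[, 2], ...)
}

# Circular-arc path at fixed radius from the pool centre, spanning polar
# angles [from, to] (degrees, clockwise-increasing), constant speed.
polar_arc_track <- function(radius, from, to, speed = 20, dt = 0.05, ...) {
  arc_len <- abs(to - from) * pi / 180 * radius
  n <- max(2L, ceiling(arc_len / (speed * dt)) + 1L)
  a <- seq(from, to, length.out = n) * pi / 180
  make_track(seq_len(n) * dt, radius * sin(a), radius * cos(a), ...)
}

# Smooth bounded random walk inside the pool: heading random walk with
# wall reflection. Used as the neutral fixture for metrics oracles.
random_walk_track <- function(duration = 45, speed = 18, dt = 0.1,
                              turn_sd = 20, r_max = 82, ...) {
  n <- round(duration / dt)
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, -40, 40)
  y[1] <- stats::runif(1, -40, 40)
  h <- stats::runif(1, 0, 360)
  for (i in 2:n) {
    h <- h + stats::rnorm(1, 0, turn_sd)
    nx <- x[i - 1] + speed * dt * sin(h * pi / 180)
    ny <- y[i - 1] + speed * dt * cos(h * pi / 180)
    if (sqrt(nx^2 + ny^2) > r_max) {
      h <- (atan2(-x[i - 1], -y[i - 1]) * 180 / pi) + stats::rnorm(1, 0, 20)
      nx <- x[i - 1] + speed * dt * sin(h * pi / 180)
      ny <- y[i - 1] + speed * dt * cos(h * pi / 180)
    }
    x[i] <- nx; y[i] <- ny
  }
  make_track((seq_len(n) - 1) * dt, x, y, ...)
}

# Rotate a track (compass-clockwise) by `angle` degrees about the pool
# centre; pair with a pool_config whose platform bearing is rotated the
# same way.
rotate_track <- function(track, angle) {
  rad <- -angle * pi / 180
  x <- track$x * cos(rad) - track$y * sin(rad)
  y <- track$x * sin(rad) + track$y * cos(rad)
  swimstrat:::new_swim_track(tibble::tibble(t = track$t, x = x, y = y),
                             track_meta(track))
}
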