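cfg <- pool_config()

test_that("track files round-trip and invalid files are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.csv")
  writeLines(c("t,x,y", "0,0,0", "0.5,5,0", "1.0,10,0"), f)
  tr <- read_track(f)
  expect_s3_class(tr, "swim_track")
  expect_equal(nrow(tr), 3)

  # a NaN row among many is dropped with a warning
  rows <- sprintf("%.1f,%.1f,0", seq(0, 9.9, 0.1), seq(0, 9.9, 0.1))
  rows[50] <- "4.9,NaN,0"
  writeLines(c("t,x,y", rows), f)
  expect_warning(tr2 <- read_track(f), "dropped 1")
  expect_equal(nrow(tr2), 99)

  # too many bad rows is a load failure naming the defect
  bad <- rows
  bad[2:30] <- "NaN,NaN,NaN"
  writeLines(c("t,x,y", bad), f)
  expect_error(read_track(f), "non-finite")

  # long tracking gaps invalidate the trial
  writeLines(c("t,x,y", "0,0,0", "0.1,1,0", "5,2,0"), f)
  expect_error(read_track(f), "gap")

  # write -> read reproduces coordinates to 1e-6 cm
  set.seed(3)
  orig <- random_walk_track(duration = 10)
  write_track(orig, f)
  back <- read_track(f)
  expect_lt(max(abs(back$x - orig$x)), 1e-6)
  expect_lt(max(abs(back$y - orig$y)), 1e-6)
})

test_that("resampling preserves endpoints, shortens paths, and is idempotent", {
  tr <- straight_track(c(0, -60), c(0, 0))
  rs <- resample_track(tr, dt = 0.025)
  expect_equal(rs$t[1], tr$t[1])
  expect_equal(rs$t[nrow(rs)], tr$t[nrow(tr)])
  expect_true(all(abs(rs$x) < 1e-9)) # collinear
  expect_equal(diff(rs$t), rep(0.025, nrow(rs) - 1), tolerance = 1e-9)

  # identity on an already-uniform track at the same dt
  rs2 <- resample_track(rs, dt = 0.025)
  expect_equal(rs2$x, rs$x)
  expect_equal(rs2$t, rs$t)

  # triangle inequality: resampling never lengthens the polyline
  set.seed(4)
  for (i in 1:20) {
    w <- random_walk_track(duration = 20)
    r <- resample_track(w, dt = 0.35)
    len0 <- sum(sqrt(diff(w$x)^2 + diff(w$y)^2))
    len1 <- sum(sqrt(diff(r$x)^2 + diff(r$y)^2))
    expect_lte(len1, len0 + 1e-9)
  }

  expect_error(resample_track(tr, dt = 100), "larger")
})

test_that("smoothing is identity for window 1, exact on lines, and denoises", {
  tr <- straight_track(c(-30, -30), c(30, 30))
  expect_equal(smooth_track(tr, 1), tr)
  sm <- smooth_track(tr, 7)
  expect_equal(sm$x, tr$x, tolerance = 1e-12) # symmetric windows keep lines
  expect_equal(sm$y, tr$y, tolerance = 1e-12)

  set.seed(5)
  noisy <- tr
  noisy$x <- noisy$x + stats::rnorm(nrow(tr), 0, 0.5)
  noisy <- swimstrat:::new_swim_track(noisy, track_meta(tr))
  smn <- smooth_track(noisy, 7)
  rms_before <- sqrt(mean((noisy$x - tr$x)^2))
  rms_after <- sqrt(mean((smn$x - tr$x)^2))
  expect_lt(rms_after, rms_before)

  expect_error(smooth_track(tr, 4), "odd")
  expect_error(smooth_track(tr, 9999), "exceeds")
})

test_that("headings measure bearings and signed turns correctly", {
  # straight track: no turns
  h <- track_headings(resample_track(straight_track(c(0, -60), c(0, 20)), 0.1))
  expect_true(all(abs(h$turns$turn) < 1e-9))
  expect_equal(h$steps$bearing[1], 0, tolerance = 1e-9)

  # three 90-degree left corners on a square path
  sq <- make_track(
    t = seq(0, 3.9, by = 0.1),
    x = c(seq(0, 18, 2), rep(20, 10), seq(20, 2, -2), rep(0, 10)),
    y = c(rep(0, 10), seq(0, 18, 2), rep(20, 10), seq(20, 2, -2))
  )
  # traversed clockwise in compass terms this square turns -90 three times
  h2 <- track_headings(sq)
  big <- h2$turns$turn[abs(h2$turns$turn) > 45]
  expect_equal(big, c(-90, -90, -90))

  # analytic 270-degree arc: turns sum to 270
  a <- seq(0, 271, by = 1) * pi / 180 # 271 chords: turns span 270 degrees
  arc <- make_track(seq_along(a) * 0.05, 20 * sin(a), 20 * cos(a))
  h3 <- track_headings(arc, min_step = 0.1)
  expect_equal(sum(h3$turns$turn), 270, tolerance = 1e-6)
})

test_that("turns are rotation-equivariant and reparameterization-invariant", {
  set.seed(6)
  w <- random_walk_track(duration = 20)
  h <- track_headings(resample_track(w, 0.1))
  hr <- track_headings(resample_track(rotate_track(w, 137), 0.1))
  expect_equal(hr$turns$turn, h$turns$turn, tolerance = 1e-9)

  # uniform time dilation leaves the geometric turn sequence unchanged
  w2 <- swimstrat:::new_swim_track(
    tibble::tibble(t = w$t * 2, x = w$x, y = w$y),
    list(trial_duration = 180)
  )
  h2 <- track_headings(resample_track(w2, 0.2))
  expect_equal(sum(abs(h2$turns$turn)), sum(abs(h$turns$turn)), tolerance = 1e-6)
})

test_that("track validation rejects malformed inputs", {
  expect_error(swim_track(data.frame(t = c(0, 0), x = 0:1, y = 0)), "increasing")
  expect_error(swim_track(data.frame(t = 0, x = 0, y = 0)), "at least 2")
  expect_error(swim_track(data.frame(t = 0:1, x = c(0, NA), y = 0)), "non-finite")
  expect_error(
    swim_track(data.frame(t = c(0, 95), x = 0:1, y = 0), trial_duration = 90),
    "duration"
  )
  expect_error(swim_track(data.frame(t = 0:1, x = c(0, 120), y = 0), cfg = cfg),
               "outside the pool")
})
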