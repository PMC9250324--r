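cfg <- pool_config()
params <- classifier_params()

detect_on <- function(track, what = c("curves", "nonsense"), p = params) {
  pp <- preprocess_track(track, p)
  switch(match.arg(what),
         curves = detect_curves(pp$headings, p),
         nonsense = detect_nonsense(pp$headings, p))
}

test_that("curve detection is strict at the 90-degree threshold", {
  for (case in list(list(80, 0L), list(90, 0L), list(91, 1L))) {
    tr <- arc_track(case[[1]])
    ev <- detect_on(tr, "curves")
    expect_equal(nrow(ev), case[[2]],
                 info = sprintf("arc of %g degrees", case[[1]]))
  }
  # a sustained 120-degree left (counter-clockwise) arc: one event,
  # negative magnitude
  ev <- detect_on(arc_track(-120), "curves")
  expect_equal(nrow(ev), 1)
  expect_lt(ev$magnitude, -90)
  expect_equal(ev$magnitude, -120, tolerance = 10)
})

test_that("separated same-direction arcs yield one event each", {
  # three 100-degree arcs separated by long straights
  tr <- arc_track(100, lead = 3, tail = 0, start = c(-60, -60), heading = 20)
  seg2 <- arc_track(100, lead = 3, tail = 0,
                    start = c(tr$x[nrow(tr)], tr$y[nrow(tr)]),
                    heading = 120)
  seg2$t <- seg2$t + tr$t[nrow(tr)]
  seg3 <- arc_track(100, lead = 3, tail = 3,
                    start = c(seg2$x[nrow(seg2)], seg2$y[nrow(seg2)]),
                    heading = 220)
  seg3$t <- seg3$t + seg2$t[nrow(seg2)]
  joined <- make_track(c(tr$t, seg2$t[-1], seg3$t[-1]),
                       c(tr$x, seg2$x[-1], seg3$x[-1]),
                       c(tr$y, seg2$y[-1], seg3$y[-1]))
  ev <- detect_on(joined, "curves")
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$magnitude > 90))
  expect_equal(ev$magnitude, rep(100, 3), tolerance = 12)
})

test_that("zigzags are alternating sharp swings; straights are silent", {
  # four alternating 60-degree swings with short legs
  pts <- list(c(-40, -40))
  h <- 0
  pos <- c(-40, -40)
  dirv <- function(h) c(sin(h * pi / 180), cos(h * pi / 180))
  step <- function(d, n) for (i in 1:n) { pos <<- pos + 2 * dirv(d); pts[[length(pts) + 1]] <<- pos }
  step(h, 20)
  for (corner in c(60, -60, 60, -60)) {
    h <- h + corner
    step(h, 8)
  }
  step(h, 20)
  m <- do.call(rbind, pts)
  zig <- make_track(seq_len(nrow(m)) * 0.1, m[, 1], m[, 2])
  # raw heading series: the swing definition acts on the turn sequence
  ev <- detect_nonsense(track_headings(zig), params)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$subtype, "zigzag")

  straight <- straight_track(c(-60, -60), c(40, 40))
  expect_equal(nrow(detect_on(straight, "nonsense")), 0)
  expect_equal(nrow(detect_on(straight, "curves")), 0)
})

test_that("a 450-degree spiral is one nonsense event, not a curve", {
  sp <- arc_track(450, start = c(-20, -20), heading = 45)
  nonsense <- detect_on(sp, "nonsense")
  expect_equal(nrow(nonsense), 1)
  expect_equal(nonsense$subtype, "spiral")
  curves <- detect_on(sp, "curves")
  merged <- merge_events(curves, nonsense)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$kind, "nonsense")
})

test_that("peripheral seeking needs >3 octants in zone 3 or >1 in zone 4", {
  # zone-3 dashes spanning exactly 1-4 octants: start 25 degrees before
  # the 247.5 boundary and end 5 degrees short of the n-th boundary
  for (n_oct in 1:4) {
    span <- (n_oct - 1) * 45 + 20
    tr <- polar_arc_track(60, 247.5 - 25, 247.5 - 25 + span)
    ev <- detect_peripheral(resample_track(tr, 0.1), cfg, params)
    expect_equal(nrow(ev), as.integer(n_oct > 3),
                 info = sprintf("zone 3, %d octants", n_oct))
  }
  # zone-4 episodes spanning 1 then 2 octants
  one <- polar_arc_track(82, 250, 280)
  expect_equal(nrow(detect_peripheral(resample_track(one, 0.1), cfg, params)), 0)
  two <- polar_arc_track(82, 250, 300)
  ev2 <- detect_peripheral(resample_track(two, 0.1), cfg, params)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$subtype, "zone4")
})

test_that("peripheral episode counting matches a brute-force scan", {
  set.seed(10)
  for (i in 1:20) {
    w <- random_walk_track(duration = 40, r_max = 86)
    rs <- resample_track(w, 0.1)
    ev <- detect_peripheral(rs, cfg, params)
    zone <- zone_of(rs$x, rs$y, cfg)
    oct <- octant_of(rs$x, rs$y, cfg)
    count <- 0L
    for (z in c(3L, 4L)) {
      lim <- if (z == 3L) 3L else 1L
      r <- rle(zone == z)
      e <- cumsum(r$lengths); s <- e - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k] && length(unique(oct[s[k]:e[k]])) > lim) count <- count + 1L
      }
    }
    expect_equal(nrow(ev), count)
  }
})

test_that("merging keeps disjoint events and subsumes overlapped curves", {
  curves <- swimstrat:::new_events(
    kind = c("curve", "curve"), subtype = c("curve", "curve"),
    t_start = c(1, 10), t_end = c(2, 12),
    i_start = c(1L, 50L), i_end = c(5L, 60L), magnitude = c(120, 150)
  )
  nonsense <- swimstrat:::new_events(
    kind = "nonsense", subtype = "spiral",
    t_start = 9.5, t_end = 13, i_start = 48L, i_end = 65L, magnitude = 400
  )
  merged <- merge_events(curves, nonsense)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$kind, c("curve", "nonsense")) # sorted by start time
  expect_equal(merged$t_start, c(1, 9.5))
})
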