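#' Archetype specification for synthetic trials
#'
#' Describes one synthetic swim trial to construct: the target
#' search-strategy category and the number of trajectory changes of each
#' kind to embed. Ground truth is defined by construction (the generator
#' inserts exactly the requested change motifs and keeps all navigation
#' below the classifier's turn-significance threshold), never by running
#' the classifier.
#'
#' For effective categories (A-G) the change counts must total within the
#' category's precision band (A: 0, B/E: 1-3, C/F: 4-6, D/G: 7+). For the
#' ineffective categories the counts must be zero: H and I trials are
#' built from sub-threshold wandering (confined to at most three contiguous
#' octants for H, spread across the pool for I) and J trials from
#' wall-following, whose change events are a by-product of the geometry
#' rather than a constructible knob.
#'
#' @param target_category One of `"A"`-`"J"`.
#' @param n_curves,n_zigzags,n_spirals,n_peripheral Number of trajectory
#'   changes of each kind to embed (defaults fill the band with curves).
#' @param start_octant Release octant (3-7, i.e. away from the platform).
#' @param speed Swim speed (cm/s).
#' @param noise_sd Gaussian positional noise added per sample (cm);
#'   emulates tracking jitter.
#' @param trial_duration Trial length (s).
#' @param seed Optional integer for reproducible generation.
#' @return An `archetype_spec` object.
#' @export
archetype_spec <- function(target_category,
                           n_curves = NA, n_zigzags = NA, n_spirals = NA,
                           n_peripheral = NA,
                           start_octant = 4, speed = 20, noise_sd = 0.5,
                           trial_duration = 90, seed = NULL) {
  target_category <- match.arg(target_category, LETTERS[1:10])
  counts <- c(curve = n_curves, zigzag = n_zigzags,
              spiral = n_spirals, peripheral = n_peripheral)
  if (all(is.na(counts))) {
    default_total <- c(A = 0, B = 2, C = 5, D = 7, E = 2, F = 5, G = 7,
                       H = 0, I = 0, J = 0)[[target_category]]
    counts <- c(curve = default_total, zigzag = 0, spiral = 0, peripheral = 0)
  }
  counts[is.na(counts)] <- 0
  band <- category_band(target_category)
  total <- sum(counts)
  if (target_category %in% LETTERS[1:7]) {
    if (total < band[1] || total > band[2]) {
      stop(sprintf("category %s requires %d-%d trajectory changes, got %d",
                   target_category, band[1], band[2], total), call. = FALSE)
    }
  } else if (total != 0) {
    stop("change counts are not constructible for ineffective categories (H, I, J)",
         call. = FALSE)
  }
  if (!start_octant %in% 3:7) {
    stop("start_octant must be in 3:7 (release points away from the platform)",
         call. = FALSE)
  }
  spec <- structure(
    list(target_category = target_category,
         n_curves = unname(counts["curve"]),
         n_zigzags = unname(counts["zigzag"]),
         n_spirals = unname(counts["spiral"]),
         n_peripheral = unname(counts["peripheral"]),
         start_octant = start_octant, speed = speed, noise_sd = noise_sd,
         trial_duration = trial_duration, seed = seed),
    class = "archetype_spec"
  )
  est <- archetype_time_estimate(spec)
  if (est > 0.92 * trial_duration) {
    stop(sprintf(
      "infeasible archetype: ~%.0f s of construction does not fit a %.0f s trial at %.0f cm/s",
      est, trial_duration, speed), call. = FALSE)
  }
  spec
}

# Precision band limits (upper bound 99 stands for "7 or more").
category_band <- function(category) {
  switch(category,
         A = c(0, 0), B = c(1, 3), C = c(4, 6), D = c(7, 99),
         E = c(1, 3), F = c(4, 6), G = c(7, 99),
         c(0, 0))
}

# Coarse time budget (s) for a spec, scaled to 20 cm/s.
archetype_time_estimate <- function(spec) {
  pooled <- as.character(strategy_parameters(spec$target_category)$pooled)
  approach <- switch(pooled, direct = 20, indirect = 8, 0)
  final <- if (pooled %in% c("direct", "indirect")) 8 else 0
  scale <- 20 / spec$speed
  (approach + final +
      5 * spec$n_curves + 8 * spec$n_zigzags + 8 * spec$n_spirals +
      14 * spec$n_peripheral) * scale
}

polar_point <- function(bearing, radius) radius * bearing_dir(bearing)

# --- motif construction ----------------------------------------------------

# One deliberately inserted trajectory change at the current position.
# Straight buffers isolate the motif's sharp turns from everything else.
# The entry bearing is offset so the motif's net sweep straddles
# `centre_bearing` (facing the pool centre) and its exit heading stays
# roughly inward, bounding outward drift of the tour.
place_motif <- function(T, kind, cfg) {
  # curve/spiral sweeps straddle the inward bearing; the zigzag marches
  # ~55 cm at ~45 deg off-inward, staying in the central pool and ending
  # without outward momentum. The rotation sign is chosen so the motif's
  # entry heading points away from the platform: alignment and the motif
  # itself run open-loop, and must never drift toward the platform disc.
  pc <- platform_center(cfg)
  # aim base: the inward bearing, pushed at least 40 deg off the platform
  # bearing so no open-loop march can head for the platform disc; the
  # clamp side is fixed at the first computation so later re-aims cannot
  # flip across the platform bearing
  safe_base <- function() {
    p <- tt_pos(T)
    cb <- bearing_of(-p[1], -p[2])
    pb <- bearing_of(pc[["x"]] - p[1], pc[["y"]] - p[2])
    d <- wrap_turn(cb - pb)
    if (abs(d) < 40) (pb + if (d >= 0) 40 else -40) %% 360 else cb
  }
  off_of <- function(sg) switch(kind, curve = -sg * 60, spiral = -sg * 90,
                                zigzag = sg * 24, 0)
  # the zigzag translates ~21 deg beyond its entry bearing: judge its
  # platform clearance on the march direction, not the entry
  crit_of <- function(sg) if (kind == "zigzag") sg * 45 else off_of(sg)
  p <- tt_pos(T)
  pb <- bearing_of(pc[["x"]] - p[1], pc[["y"]] - p[2])
  base <- safe_base()
  clearance <- vapply(c(1, -1), function(sg) {
    abs(wrap_turn(base + crit_of(sg) - pb))
  }, numeric(1))
  sgn <- c(1, -1)[which.max(clearance)]
  offset <- off_of(sgn)
  tt_steer_heading(T, base + offset)
  # the alignment turn itself displaces the turtle by up to two turning
  # radii, so re-aim from where it actually ended up
  tt_steer_heading(T, safe_base() + offset)
  tt_straight(T, 0.8)
  if (kind == "curve") {
    tt_arc(T, sgn * 120)
  } else if (kind == "spiral") {
    tt_arc(T, sgn * 450)
  } else if (kind == "zigzag") {
    # legs no shorter than the analysis smoothing window, so adjacent
    # swings stay resolvable after preprocessing
    for (j in 1:4) {
      tt_step(T, sgn * (-1)^(j - 1) * 90)
      tt_straight(T, 0.7)
    }
  }
  tt_straight(T, 0.8)
  tt_steer_heading(T, safe_base())
  invisible(T)
}

# Peripheral-seeking excursion, fully servo-driven so the wall is never
# overshot: stage in the central south, blend tangential, climb onto the
# wall ring with the wall-following controller (sweeping clockwise), then
# descend with the same controller. The zone-4 stretch spans well over one
# octant boundary, registering exactly one peripheral event.
place_peripheral <- function(T, cfg) {
  stage_polar <- 180
  for (k in 1:2) {
    tt_steer_to(T, polar_point(stage_polar, 40), cfg, stop_dist = 6,
                wall_limit = 70)
    p <- tt_pos(T)
    if (sqrt(p[1]^2 + p[2]^2) >= 30) break
  }
  p <- tt_pos(T)
  tt_steer_heading(T, bearing_of(p[1], p[2]) + 90)
  # climb to the wall, hug it for 55 degrees (any arc of 45+ degrees
  # crosses an octant boundary, and under ~90 degrees stays within three
  # octants: exactly one peripheral event), then descend
  tt_wall_follow(T, r_target = 0.91 * pool_radius(cfg), until_r = 78,
                 sweep = 170, tilt_max = 45)
  tt_wall_follow(T, r_target = 0.91 * pool_radius(cfg), sweep = 55)
  tt_wall_follow(T, r_target = 40, until_r = 55, tilt_max = 45)
  p <- tt_pos(T)
  a_out <- bearing_of(p[1], p[2])
  tt_steer_to(T, polar_point(a_out + 10, 42), cfg, stop_dist = 4,
              wall_limit = 70, loose = TRUE)
  invisible(T)
}

# Clip the peripheral platform zone before the first motif: cut through
# the central pool, visit the point of the platform ring (d_pass cm from
# the platform) that faces the pool centre, and exit radially away from
# the platform toward the motif region. The visit guarantees a zone-1
# entry (d_pass + stop tolerance stays well inside the zone-1 radius)
# while never approaching the platform disc itself.
ring_visit <- function(T, cfg, d_pass = 30) {
  pc <- platform_center(cfg)
  ctr_bear <- (cfg$platform_bearing + 180) %% 360 # platform -> pool centre
  Q <- c(pc[["x"]], pc[["y"]]) + d_pass * bearing_dir(ctr_bear)
  p <- tt_pos(T)
  c0 <- polar_point(bearing_of(p[1], p[2]), 30)
  tt_steer_to(T, c0, cfg, stop_dist = 4, loose = TRUE)
  tt_steer_to(T, Q, cfg, stop_dist = 3, avoid_platform = FALSE)
  exit <- Q + 35 * bearing_dir(ctr_bear)
  tt_steer_to(T, exit, cfg, stop_dist = 6, avoid_platform = FALSE, loose = TRUE)
  invisible(T)
}

# Tour of the open-water motif region (the pool half opposite the
# platform): visit ring anchors, placing one motif at each. `rot` rotates
# the anchor sequence (used by the construction-validation retry loop).
# Returns the time windows of the wall (peripheral) excursions.
motif_tour <- function(T, kinds, cfg, rot = 0, ring_r = 32) {
  ring_polar <- rep(c(225, 192, 258, 207, 243, 177, 273, 222, 237, 195), 3)
  if (rot > 0) ring_polar <- c(ring_polar[-seq_len(rot)], ring_polar[seq_len(rot)])
  pc <- platform_center(cfg)
  away <- (cfg$platform_bearing + 180) %% 360
  windows <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    if (kind == "peripheral") {
      t0 <- tt_time(T)
      place_peripheral(T, cfg)
      windows[[length(windows) + 1L]] <- c(t0, tt_time(T))
    } else {
      anchor <- polar_point(away + wrap_turn(ring_polar[i] - 225), ring_r)
      tt_steer_to(T, anchor, cfg, stop_dist = 3, wall_limit = 70, loose = TRUE)
      # a loose arrival can leave the turtle near the platform or drifted
      # out toward the wall; retreat to the far-side focus point before
      # committing an open-loop motif
      focus <- polar_point(away, 35)
      for (k in 1:2) {
        p <- tt_pos(T)
        dp <- sqrt((p[1] - pc[["x"]])^2 + (p[2] - pc[["y"]])^2)
        if (dp >= 50 && sqrt(p[1]^2 + p[2]^2) <= 60) break
        dist <- sqrt(sum((p - focus)^2))
        tt_steer_for(T, focus, dur = dist / T$v + 1.2, cfg)
      }
      place_motif(T, kind, cfg)
    }
  }
  windows
}

# Kind sequence for the requested counts; peripheral excursions last (they
# leave and re-enter the open-water motif region).
motif_kinds <- function(spec) {
  c(rep("curve", spec$n_curves),
    rep("zigzag", spec$n_zigzags),
    rep("spiral", spec$n_spirals),
    rep("peripheral", spec$n_peripheral))
}

# --- trajectory generator --------------------------------------------------

#' Generate a synthetic swim trial with known ground truth
#'
#' Constructs a trajectory realising an [archetype_spec()]: straight or
#' gently steered navigation (always below the classifier's
#' turn-significance threshold), deliberately inserted change motifs (sharp
#' arcs, zigzags, spirals, wall excursions), and, for effective categories,
#' a final approach onto the platform. Direct categories clip the
#' peripheral platform zone on a tangent pass before the first motif;
#' indirect categories place their first motif before ever nearing the
#' platform ring. Gaussian positional noise is added last.
#'
#' @param spec An [archetype_spec()].
#' @param cfg A [pool_config()].
#' @return A list:
#'   \describe{
#'     \item{track}{the [swim_track()];}
#'     \item{truth}{a one-row tibble with the constructed ground truth:
#'       `category`, `pooled`, `effective`, `directionality`, and
#'       `n_changes` (`NA` for J, whose wall-hug produces peripheral events
#'       as a by-product of the geometry).}
#'   }
#' @examples
#' cfg <- pool_config()
#' gen <- generate_archetype(archetype_spec("E", noise_sd = 0, seed = 7), cfg)
#' gen$truth$category
#' @export
generate_archetype <- function(spec, cfg = pool_config()) {
  stopifnot(inherits(spec, "archetype_spec"), inherits(cfg, "pool_config"))
  if (!is.null(spec$seed)) {
    withr::with_seed(spec$seed, generate_archetype_impl(spec, cfg))
  } else {
    generate_archetype_impl(spec, cfg)
  }
}

generate_archetype_impl <- function(spec, cfg) {
  cat <- spec$target_category
  pooled <- as.character(strategy_parameters(cat)$pooled)
  build <- function(variant) build_archetype_track(spec, cfg, pooled, variant)

  if (pooled %in% c("direct", "indirect")) {
    # open-loop motif construction can, for unlucky layouts, brush the
    # platform disc or sweep the outer zones in transit; validate the
    # geometry of the built path and retry with a rotated anchor layout
    built <- NULL
    for (variant in 0:9) {
      candidate <- build(variant)
      if (construction_valid(candidate, cfg, spec)) {
        built <- candidate
        break
      }
    }
    if (is.null(built)) {
      stop("infeasible archetype: no valid construction found for this spec",
           call. = FALSE)
    }
  } else {
    built <- build(0)
    if (!construction_valid(built, cfg, spec)) {
      stop("infeasible archetype: no valid construction found for this spec",
           call. = FALSE)
    }
  }

  meta <- list(
    animal_id = NA_character_, group = NA_character_, day = NA_integer_,
    trial_index = NA_integer_,
    trial_type = "acquisition",
    trial_duration = spec$trial_duration,
    start_octant = spec$start_octant
  )
  track <- tt_track(built$T, meta, noise_sd = spec$noise_sd, cfg = cfg)
  n_changes <- if (cat %in% c("I", "J")) {
    # wandering across the pool (I) and wall-hugging (J) produce change
    # events as a by-product of the geometry, not as a constructible count
    NA_integer_
  } else {
    as.integer(spec$n_curves + spec$n_zigzags + spec$n_spirals + spec$n_peripheral)
  }
  truth <- strategy_parameters(cat)
  truth$n_changes <- n_changes
  list(track = track, truth = truth)
}

# One construction attempt; returns the turtle plus the phase bookkeeping
# the geometric validator needs.
build_archetype_track <- function(spec, cfg, pooled, variant) {
  cat <- spec$target_category
  a0 <- 45 * spec$start_octant
  start <- polar_point(a0, 0.89 * pool_radius(cfg))
  heading0 <- if (cat == "J") (a0 + 90) %% 360 else (a0 + 180) %% 360
  T <- tt_new(start[1], start[2], heading0, spec$speed, spec$trial_duration)
  pc <- platform_center(cfg)
  kinds <- motif_kinds(spec)
  windows <- list()
  t_final <- NA_real_

  if (pooled == "direct") {
    if (length(kinds) > 0) {
      # clip zone 1 first, then commit the changes
      ring_visit(T, cfg)
      windows <- motif_tour(T, kinds, cfg, rot = variant,
                            ring_r = c(32, 28, 36, 30, 34)[variant %% 5 + 1])
    }
    t_final <- tt_time(T)
    tt_steer_to(T, c(pc[["x"]], pc[["y"]]), cfg, stop_dist = 2,
                avoid_platform = FALSE)
    tt_straight(T, 0.3)
  } else if (pooled == "indirect") {
    windows <- motif_tour(T, kinds, cfg, rot = variant,
                          ring_r = c(32, 28, 36, 30, 34)[variant %% 5 + 1])
    t_final <- tt_time(T)
    tt_steer_to(T, c(pc[["x"]], pc[["y"]]), cfg, stop_dist = 2,
                avoid_platform = FALSE)
    tt_straight(T, 0.3)
  } else if (cat == "H") {
    # patrol loop spanning the start octant and its neighbours, away from
    # the wall and from the unstable pool centre
    sc <- a0
    anchors <- purrr::map2(
      sc + c(-26, 0, 26, 30, 0, -30),
      c(42, 36, 42, 54, 58, 54),
      polar_point
    )
    tt_wander(T, anchors, cfg, until_time = spec$trial_duration,
              wall_limit = 66, min_r = 24)
  } else if (cat == "I") {
    anchors <- purrr::map2(c(0, 85, 160, 215, 285), rep(40, 5), polar_point)
    tt_wander(T, anchors, cfg, until_time = spec$trial_duration)
  } else { # J: thigmotaxis
    # ring radius outside the reach of the platform ring (zone 1), so the
    # wall-hug stays in zone 4 even where it passes the platform bearing
    tt_wall_follow(T, r_target = 0.94 * pool_radius(cfg),
                   until_time = spec$trial_duration)
  }
  list(T = T, t_final = t_final, windows = windows)
}

# Geometric validation of a noise-free construction against the invariants
# the archetype is built to satisfy. Pure geometry on the path: the
# classifier is never consulted, so ground truth stays construction-defined.
construction_valid <- function(built, cfg, spec) {
  T <- built$T
  idx <- seq_len(T$n)
  x <- T$x[idx]; y <- T$y[idx]
  t <- (idx - 1L) * T$dt
  r <- sqrt(x^2 + y^2)
  if (max(r) > pool_radius(cfg) + cfg$wall_tolerance - 0.5) return(FALSE)

  cat <- spec$target_category
  pooled <- as.character(strategy_parameters(cat)$pooled)
  pc <- platform_center(cfg)
  d_plat <- sqrt((x - pc[["x"]])^2 + (y - pc[["y"]])^2)

  if (pooled %in% c("direct", "indirect")) {
    pre <- t < (built$t_final %||% Inf)
    # the platform disc (radius platform_diameter/2) must stay untouched
    # until the scheduled final approach, with margin for tracking noise
    if (any(d_plat[pre] < cfg$platform_diameter / 2 + 2.5)) return(FALSE)
    # outside the designated wall excursions, transit must not sweep the
    # outer zones across octants (that would read as peripheral seeking)
    in_window <- rep(FALSE, length(t))
    for (w in built$windows) in_window <- in_window | (t >= w[1] & t <= w[2])
    zone <- zone_of(x, y, cfg)
    oct <- octant_of(x, y, cfg)
    for (z in c(3L, 4L)) {
      limit <- if (z == 3L) 3L else 1L
      inz <- zone == z & !in_window
      # bridge sub-half-second interruptions: coarser analysis sampling
      # would merge them into one episode
      rr <- rle(inz)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1L
      gap <- as.integer(ceiling(0.5 / T$dt))
      for (k in seq_along(rr$values)) {
        if (!rr$values[k] && rr$lengths[k] <= gap &&
            k > 1L && k < length(rr$values)) {
          inz[starts[k]:ends[k]] <- TRUE
        }
      }
      rr <- rle(inz)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1L
      for (k in seq_along(rr$values)) {
        if (!rr$values[k]) next
        if (length(unique(oct[starts[k]:ends[k]])) > limit) return(FALSE)
      }
    }
  } else if (cat == "H") {
    if (!octants_localized(unique(octant_of(x, y, cfg)))) return(FALSE)
    if (any(d_plat < cfg$platform_diameter / 2 + 2.5)) return(FALSE)
  } else if (cat == "I") {
    if (any(d_plat < cfg$platform_diameter / 2 + 2.5)) return(FALSE)
  } else { # J
    if (mean(zone_of(x, y, cfg) == 4L) < 0.98) return(FALSE)
  }
  TRUE
}
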