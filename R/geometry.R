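#' Octant, zone, and quadrant membership
#'
#' The pool is divided into eight 45-degree octants by the N, NE, E, SE, S,
#' SW, W, and NW axes; into four quadrants by the N-S and E-W axes; and into
#' five analysis zones: zone 0 is the platform disc, zone 1 the peripheral
#' platform disc (both centred on the platform), and zones 2-4 are discs
#' concentric with the pool (central, intermediate, and outer/thigmotaxis
#' areas). Zone membership uses the precedence 0 > 1 > 2 > 3 > 4, so every
#' in-pool point belongs to exactly one zone.
#'
#' Octant 0 is the 45-degree sector centred on north, octants counted
#' clockwise (NE axis lies in octant 1 under the default configuration).
#' Sectors are half-open clockwise, `[start, end)`. Quadrant 0 is NE
#' (bearings `[0, 90)`), counted clockwise.
#'
#' @param x,y Point coordinates, pool-centred cm (vectorised).
#' @param cfg A [pool_config()].
#' @return An integer vector: octant index 0-7, zone id 0-4, or quadrant id
#'   0-3. Points farther outside the pool wall than `cfg$wall_tolerance`
#'   raise an error (corrupt track).
#' @examples
#' cfg <- pool_config()
#' octant_of(0, 50, cfg)      # due north -> 0
#' zone_of(0, 0, cfg)         # pool centre -> central pool zone
#' quadrant_of(31.8, 31.8, cfg) == correct_quadrant(cfg)
#' @export
octant_of <- function(x, y, cfg) {
  check_in_pool(x, y, cfg)
  b <- (bearing_of(x, y) - cfg$north_reference) %% 360
  as.integer(floor(((b + 22.5) %% 360) / 45))
}

#' @rdname octant_of
#' @export
zone_of <- function(x, y, cfg) {
  check_in_pool(x, y, cfg)
  pc <- platform_center(cfg)
  d_plat <- sqrt((x - pc[["x"]])^2 + (y - pc[["y"]])^2)
  d_pool <- sqrt(x^2 + y^2)
  zone <- rep.int(4L, length(x))
  zone[d_pool <= cfg$zone3_diameter / 2] <- 3L
  zone[d_pool <= cfg$zone2_diameter / 2] <- 2L
  zone[d_plat <= cfg$zone1_diameter / 2] <- 1L
  zone[d_plat <= cfg$platform_diameter / 2] <- 0L
  zone
}

#' @rdname octant_of
#' @export
quadrant_of <- function(x, y, cfg) {
  check_in_pool(x, y, cfg)
  b <- (bearing_of(x, y) - cfg$north_reference) %% 360
  as.integer(floor(b / 90))
}

#' @rdname octant_of
#' @return `correct_quadrant()`: the quadrant id containing the platform
#'   centre (NE, id 0, under the defaults).
#' @export
correct_quadrant <- function(cfg) {
  pc <- platform_center(cfg)
  quadrant_of(pc[["x"]], pc[["y"]], cfg)
}

# Reject points beyond the pool wall plus tracking tolerance.
check_in_pool <- function(x, y, cfg) {
  stopifnot(inherits(cfg, "pool_config"))
  r <- sqrt(x^2 + y^2)
  bad <- !is.finite(r) | r > pool_radius(cfg) + cfg$wall_tolerance
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "point (%.2f, %.2f) lies %.2f cm outside the pool wall (tolerance %.2f cm); corrupt track?",
      x[i], y[i], r[i] - pool_radius(cfg), cfg$wall_tolerance
    ), call. = FALSE)
  }
  invisible(TRUE)
}
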