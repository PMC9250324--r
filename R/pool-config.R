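#' Pool configuration
#'
#' Describes the water maze geometry: the circular pool, the hidden escape
#' platform, and the five concentric analysis zones. Defaults reproduce a
#' standard rat maze: a 180 cm pool with a 15 cm platform on the NE axis,
#' halfway between the wall and the centre.
#'
#' Coordinates are pool-centred Cartesian centimetres with +y pointing north;
#' bearings are measured clockwise from north. Zones 0 (the platform disc)
#' and 1 (the peripheral platform disc) are centred on the platform; zones
#' 2-4 are concentric with the pool. Membership precedence is
#' 0 > 1 > 2 > 3 > 4, so the five zones partition the pool.
#'
#' @param pool_diameter Pool diameter (cm).
#' @param pool_depth Pool depth (cm, informational only).
#' @param platform_diameter Escape platform diameter (cm).
#' @param platform_bearing Compass bearing of the platform centre, degrees
#'   clockwise from north (45 = NE).
#' @param platform_radial_offset Distance (cm) from the pool centre to the
#'   platform centre.
#' @param zone1_diameter Diameter (cm) of the peripheral platform zone
#'   (zone 1), centred on the platform.
#' @param zone2_diameter Diameter (cm) of the central pool zone (zone 2).
#' @param zone3_diameter Diameter (cm) of the intermediate zone (zone 3).
#' @param zone4_diameter Diameter (cm) of the outer (thigmotaxis) zone
#'   (zone 4); equals the pool diameter.
#' @param north_reference Compass bearing (degrees) that the +y axis of the
#'   incoming coordinates corresponds to. Use this to map tracking-system
#'   frames whose "up" is not the maze's north.
#' @param wall_tolerance Distance (cm) beyond the pool wall still accepted as
#'   tracking jitter; points further out are rejected as corrupt.
#'
#' @return An object of class `pool_config` (a named list).
#' @examples
#' cfg <- pool_config()
#' platform_center(cfg)
#' @export
pool_config <- function(pool_diameter = 180,
                        pool_depth = 60,
                        platform_diameter = 15,
                        platform_bearing = 45,
                        platform_radial_offset = 45,
                        zone1_diameter = 75,
                        zone2_diameter = 90,
                        zone3_diameter = 150,
                        zone4_diameter = pool_diameter,
                        north_reference = 0,
                        wall_tolerance = 2) {
  cfg <- structure(
    list(
      pool_diameter = pool_diameter,
      pool_depth = pool_depth,
      platform_diameter = platform_diameter,
      platform_bearing = platform_bearing %% 360,
      platform_radial_offset = platform_radial_offset,
      zone1_diameter = zone1_diameter,
      zone2_diameter = zone2_diameter,
      zone3_diameter = zone3_diameter,
      zone4_diameter = zone4_diameter,
      north_reference = north_reference %% 360,
      wall_tolerance = wall_tolerance
    ),
    class = "pool_config"
  )
  validate_pool_config(cfg)
}

validate_pool_config <- function(cfg) {
  num <- vapply(cfg, function(f) is.numeric(f) && length(f) == 1L && is.finite(f), logical(1))
  if (!all(num)) {
    stop("all pool_config fields must be single finite numbers: ",
         paste(names(cfg)[!num], collapse = ", "), call. = FALSE)
  }
  with(cfg, {
    if (!(zone1_diameter < zone2_diameter &&
          zone2_diameter < zone3_diameter &&
          zone3_diameter <= zone4_diameter)) {
      stop("zone diameters must satisfy zone1 < zone2 < zone3 <= zone4", call. = FALSE)
    }
    if (zone4_diameter != pool_diameter) {
      stop("zone4_diameter must equal pool_diameter", call. = FALSE)
    }
    if (platform_radial_offset + platform_diameter / 2 >= pool_diameter / 2) {
      stop("platform must lie fully inside the pool", call. = FALSE)
    }
    if (platform_diameter >= zone1_diameter) {
      stop("platform_diameter must be smaller than zone1_diameter", call. = FALSE)
    }
  })
  cfg
}

#' @export
print.pool_config <- function(x, ...) {
  cat("<pool_config>\n")
  cat(sprintf("  pool:     %g cm diameter, %g cm deep\n", x$pool_diameter, x$pool_depth))
  cat(sprintf("  platform: %g cm diameter at bearing %g deg, %g cm from centre\n",
              x$platform_diameter, x$platform_bearing, x$platform_radial_offset))
  cat(sprintf("  zones:    0 (platform) | 1: %g | 2: %g | 3: %g | 4: %g cm diameter\n",
              x$zone1_diameter, x$zone2_diameter, x$zone3_diameter, x$zone4_diameter))
  invisible(x)
}

#' @rdname pool_config
#' @param cfg A [pool_config()].
#' @return `pool_radius()`: the pool radius in cm. `platform_center()`: a
#'   named numeric vector `c(x, y)` with the platform centre.
#' @export
pool_radius <- function(cfg) cfg$pool_diameter / 2

#' @rdname pool_config
#' @export
platform_center <- function(cfg) {
  b <- (cfg$platform_bearing - cfg$north_reference) * pi / 180
  c(x = cfg$platform_radial_offset * sin(b),
    y = cfg$platform_radial_offset * cos(b))
}

#' Read or write a pool configuration file
#'
#' Pool configurations are stored as flat YAML with keys named exactly as the
#' [pool_config()] arguments (units cm and degrees). Missing keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_pool_config()` returns a [pool_config()];
#'   `write_pool_config()` invisibly returns `path`.
#' @export
read_pool_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pool_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warning("ignoring unknown pool config keys: ", paste(extra, collapse = ", "))
  }
  do.call(pool_config, vals[intersect(names(vals), known)])
}

#' @rdname read_pool_config
#' @param cfg A [pool_config()].
#' @export
write_pool_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pool_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
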