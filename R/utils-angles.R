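# Angle conventions used throughout: bearings in degrees, clockwise from
# north (+y), in [0, 360); signed turns in (-180, 180], positive clockwise.

#' Bearing of points from the pool centre
#'
#' @param x,y Coordinates in pool-centred cm.
#' @return Bearing in degrees, clockwise from north (+y), in `[0, 360)`.
#' @keywords internal
#' @noRd
bearing_of <- function(x, y) {
  (atan2(x, y) * 180 / pi) %% 360
}

# Wrap an angle difference into (-180, 180].
wrap_turn <- function(a) {
  b <- a %% 360
  ifelse(b > 180, b - 360, b)
}

# Unit direction (dx, dy) of a compass bearing.
bearing_dir <- function(bearing) {
  rad <- bearing * pi / 180
  c(sin(rad), cos(rad))
}

# Polyline length of coordinate vectors.
path_length <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Rotate coordinates clockwise (compass sense) by `angle` degrees.
rotate_xy <- function(x, y, angle) {
  rad <- -angle * pi / 180 # compass-clockwise = mathematically negative
  list(
    x = x * cos(rad) - y * sin(rad),
    y = x * sin(rad) + y * cos(rad)
  )
}
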