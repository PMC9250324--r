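#' Plot a swim track over the pool layout
#'
#' Draws the pool wall, the analysis zones (platform zone 0, peripheral
#' platform zone 1, and the pool-concentric zones 2-3), the octant axes,
#' and the swim path coloured by time.
#'
#' @param track A [swim_track()].
#' @param cfg A [pool_config()].
#' @param show_zones Draw the zone circles.
#' @return A ggplot object.
#' @export
plot_track <- function(track, cfg = pool_config(), show_zones = TRUE) {
  circle <- function(r, cx = 0, cy = 0, n = 181) {
    a <- seq(0, 2 * pi, length.out = n)
    tibble::tibble(x = cx + r * sin(a), y = cy + r * cos(a))
  }
  pc <- platform_center(cfg)
  spokes <- purrr::map_dfr(seq(22.5, 360, by = 45), function(b) {
    d <- bearing_dir(b)
    tibble::tibble(x = 0, y = 0, xend = pool_radius(cfg) * d[1],
                   yend = pool_radius(cfg) * d[2])
  })
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = spokes,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linetype = "dotted", colour = "grey70"
    ) +
    ggplot2::geom_path(data = circle(pool_radius(cfg)),
                       ggplot2::aes(.data$x, .data$y), linewidth = 0.8)
  if (show_zones) {
    p <- p +
      ggplot2::geom_path(data = circle(cfg$zone3_diameter / 2),
                         ggplot2::aes(.data$x, .data$y), colour = "grey60") +
      ggplot2::geom_path(data = circle(cfg$zone2_diameter / 2),
                         ggplot2::aes(.data$x, .data$y), colour = "grey60") +
      ggplot2::geom_path(
        data = circle(cfg$zone1_diameter / 2, pc[["x"]], pc[["y"]]),
        ggplot2::aes(.data$x, .data$y), colour = "steelblue", linetype = "dashed"
      )
  }
  p +
    ggplot2::geom_path(
      data = circle(cfg$platform_diameter / 2, pc[["x"]], pc[["y"]]),
      ggplot2::aes(.data$x, .data$y), colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::geom_path(data = tibble::as_tibble(track),
                       ggplot2::aes(.data$x, .data$y, colour = .data$t)) +
    ggplot2::scale_colour_viridis_c(name = "time (s)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' @rdname plot_track
#' @param object,... For `autoplot`: a `swim_track` and arguments passed to
#'   `plot_track()`.
#' @method autoplot swim_track
#' @export
autoplot.swim_track <- function(object, ...) plot_track(object, ...)

#' Plot strategy frequency distributions
#'
#' Stacked per-day bars of strategy usage, faceted by group when present:
#' the standard display of how a cohort's search behaviour shifts from
#' ineffective through indirect to direct strategies with training.
#'
#' @param freq A frequency tibble from [pool_strategies()] (keys must
#'   include `day`; `group` is used for faceting when present).
#' @param fill `"pooled"` (three classes) or `"category"` (all ten).
#' @return A ggplot object.
#' @export
plot_strategy_frequencies <- function(freq, fill = c("pooled", "category")) {
  fill <- match.arg(fill)
  stopifnot("day" %in% names(freq))
  pal <- if (fill == "pooled") {
    c(direct = "#c0392b", indirect = "#2c6fbb", non_effective = "#3b3b3b")
  } else {
    stats::setNames(
      c("#7f1d1d", "#b03a2e", "#d98880", "#f1c9c0",
        "#1b4f72", "#2e86c1", "#aed6f1",
        "#1c1c1c", "#5d5d5d", "#a6a6a6"),
      LETTERS[1:10]
    )
  }
  p <- ggplot2::ggplot(freq, ggplot2::aes(
    x = factor(.data$day), y = .data$n, fill = .data[[fill]]
  )) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = pal, name = fill) +
    ggplot2::labs(x = "day", y = "fraction of trials") +
    ggplot2::theme_minimal()
  if ("group" %in% names(freq)) p <- p + ggplot2::facet_wrap(~group)
  p
}
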