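#' Plot a rod-array plan view
#'
#' Draws the rod cross-sections over the chamber plan (flow left to
#' right).
#'
#' @param rods A `rod_array` from [build_rod_array()].
#' @return A ggplot object.
#' @export
plot_rod_array <- function(rods) {
  stopifnot(inherits(rods, "rod_array"))
  spec <- attr(rods, "spec")
  r <- attr(rods, "radius_mm")
  th <- seq(0, 2 * pi, length.out = 33)
  circ <- purrr::imap_dfr(seq_len(nrow(rods)), function(k, ...) {
    tibble::tibble(
      id = k,
      x = rods$x_mm[k] + r * cos(th),
      z = rods$z_mm[k] + r * sin(th)
    )
  })
  ggplot2::ggplot(circ, ggplot2::aes(.data$z, .data$x, group = .data$id)) +
    ggplot2::geom_polygon(fill = "grey40", colour = NA) +
    ggplot2::coord_fixed(
      xlim = c(0, spec$path_length_mm),
      ylim = c(0, spec$width_mm), expand = FALSE
    ) +
    ggplot2::labs(
      x = "flow axis z (mm)", y = "width x (mm)",
      title = sprintf(
        "%.0f%% packing density, %g um rods", 100 * spec$pd, spec$fiber_um
      )
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a longitudinal slice profile
#'
#' Normalized clot fraction per segment against distance from the inlet.
#'
#' @param object A `slice_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slice_profile
#' @export
autoplot.slice_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$segment_center_mm, .data$normalized_fraction)
  ) +
    ggplot2::geom_col(width = min(object$segment_length_mm) * 0.9) +
    ggplot2::labs(
      x = "distance from inlet (mm)",
      y = "clot fraction of available void volume"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a resistance series
#'
#' ln(resistance) over time, with the clot-free baseline marked when
#' known.
#'
#' @param object A `resistance_series` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resistance_series
#' @export
autoplot.resistance_series <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(.data$time_min, .data$ln_resistance)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "ln resistance (mmHg.min/mL)") +
    ggplot2::theme_minimal()
  r0 <- attr(object, "baseline_r0")
  if (!is.null(r0)) {
    p <- p + ggplot2::geom_hline(yintercept = log(r0), linetype = "dashed")
  }
  p
}

#' Autoplot a clot probability map
#'
#' Plan-view (inlet to outlet) heat map of the rod-axis projection.
#'
#' @param object A `probability_map`.
#' @param ... Passed to [project_axis()].
#' @return A ggplot object.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, ...) {
  proj <- project_axis(object, ...)
  coords <- setdiff(names(proj), c("x_mm", "value"))
  ggplot2::ggplot(
    proj,
    ggplot2::aes(.data[[coords[1]]], .data$x_mm, fill = .data$value)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), name = "P(clot)") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      x = paste(coords[1]), y = "width x (mm)",
      title = object$label %||% NULL
    ) +
    ggplot2::theme_minimal()
}
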