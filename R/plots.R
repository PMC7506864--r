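#' Plot MAE against DSM resolution per method and sensor
#'
#' The package's analogue of the study's accuracy figure: mean absolute
#' error (mm) as a function of DSM cell size, one line per selection
#' method, one panel per sensor.
#'
#' @param smry A [summarize_sweep()] or [replicate_mean_mae()] tibble.
#' @return A ggplot object.
#' @export
plot_error_sweep <- function(smry) {
  ycol <- if ("mean_mae_mm" %in% names(smry)) "mean_mae_mm" else "mae_mm"
  ggplot2::ggplot(
    smry,
    ggplot2::aes(x = .data$cell_size_mm, y = .data[[ycol]],
                 colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_x_log10(breaks = sort(unique(smry$cell_size_mm))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sensor)) +
    ggplot2::labs(
      x = "DSM cell size (mm)", y = "MAE (mm)", colour = "selection method",
      title = "Grass height estimation error by method and DSM resolution"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_table <- function(object, ...) {
  plot_error_sweep(summarize_sweep(object))
}

#' Plot estimated against ruler-measured heights
#'
#' @param sweep A `sweep_table` filtered to the configurations of interest
#'   (e.g. each sensor at its best settings).
#' @return A ggplot object.
#' @export
plot_estimate_vs_truth <- function(sweep) {
  ggplot2::ggplot(
    sweep, ggplot2::aes(x = .data$truth_mm, y = .data$estimate_mm,
                        colour = .data$sensor)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "ruler height (mm)", y = "estimated height (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dsm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  fill = paste0(object$aggregator, " z (m)")) +
    ggplot2::theme_minimal()
}
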