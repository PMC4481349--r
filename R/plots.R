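# ggplot2 views of the result types: occupancy bars, phi-vs-distance polar
# plots, shape time series, and kinetic fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Occupancy bar plot
#'
#' @param object An `occupancy_summary` from [summarize_occupancy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_summary <- function(object, ...) {
  df <- object[!is.na(object$percent), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$percent,
                                   fill = .data$region)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(MA = "#c0392b", T = "#17a2b8",
                                          AB = "#e67e22", NB = "#27ae60",
                                          UNASSIGNED = "grey60")) +
    ggplot2::labs(x = NULL, y = "occupancy (%)") +
    ggplot2::theme_minimal()
}

#' Polar plot of gating dihedrals versus pocket distance
#'
#' The phi-versus-distance view of pre-reactive frames: angle is the gating
#' dihedral, radius the matching pocket distance, one panel per region.
#'
#' @param polar Tibble from [build_polar_records()].
#' @param angle `"phiF"` or `"phiW"`.
#' @return A ggplot object.
#' @export
plot_polar_records <- function(polar, angle = c("phiF", "phiW")) {
  angle <- match.arg(angle)
  ggplot2::ggplot(polar, ggplot2::aes(x = .data[[angle]], y = .data$radius,
                                      colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = paste(angle, "(degrees)"), y = "distance (A)") +
    ggplot2::theme_minimal()
}

#' Shape-class time series plot
#'
#' @param series Tibble from [shape_time_series()]`$series`.
#' @return A ggplot object.
#' @export
plot_shape_series <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time_ns, y = .data$coarse,
                               colour = .data$coarse)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(elongated = "#c0392b",
                                            hooked = "#f1c40f",
                                            curved = "#2980b9",
                                            unclassified = "grey60")) +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.occupancy_summary
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    concentration_uM = seq(0, max(object$data$concentration_uM), length.out = 200))
  grid$velocity <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_uM, y = .data$velocity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2980b9") +
    ggplot2::labs(x = "substrate (uM)",
                  y = "velocity (pmol min^-1 ug^-1)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.occupancy_summary
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_min = seq(0, max(object$data$time_min), length.out = 200))
  grid$signal <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#c0392b") +
    ggplot2::labs(x = "time (min)", y = "remaining substrate") +
    ggplot2::theme_minimal()
}
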