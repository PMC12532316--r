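# ggplot2 methods for the result types

#' @export
autoplot.axial_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth z (µm)", y = "absorbed energy (rel.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reception_field <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$z, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = g$z_peak, linetype = 3) +
    ggplot2::labs(x = "axial position z (mm)",
                  y = "detector response (rel.)",
                  subtitle = sprintf("DOF (FWHM) = %.2f mm", g$dof_fwhm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.detector_signal <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (µs)", y = "aggregate pressure (rel.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pressure_traces <- function(object, sensors = NULL, ...) {
  df <- tidy(object)
  if (!is.null(sensors)) df <- dplyr::filter(df, .data$sensor %in% sensors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$pressure,
                                   group = .data$sensor,
                                   colour = factor(.data$sensor))) +
    ggplot2::geom_line(show.legend = length(unique(df$sensor)) <= 10) +
    ggplot2::labs(x = "time (µs)", y = "pressure (rel.)",
                  colour = "sensor") +
    ggplot2::theme_minimal()
}

#' Plot a 2D image (MIP or B-scan) with a sensible palette
#'
#' @param img Matrix (e.g. from [mip()]).
#' @param pixel_size Pixel pitch, used for the axes (same units both axes).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_image <- function(img, pixel_size = 1, xlab = "x", ylab = "y") {
  df <- expand.grid(x = (seq_len(nrow(img)) - 1) * pixel_size,
                    y = (seq_len(ncol(img)) - 1) * pixel_size)
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = xlab, y = ylab, fill = "amplitude") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
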