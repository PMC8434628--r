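#' Plot methods
#'
#' `autoplot()` methods for the three result types: amplitude fields
#' (pressure map over the r-z half plane), sweeps (focal pressure against
#' the swept value) and fits (data points with the fitted curve).
#'
#' @param object A `fus_field`, `fus_sweep` or `fus_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.fus_field <- function(object, ...) {
  d <- as_tibble(object)
  if (object$grid$mode == "3d") {
    iy <- which.min(abs(object$grid$y_mm))
    d <- dplyr::filter(d, .data$y_mm == object$grid$y_mm[iy])
    d$r_mm <- d$x_mm
  } else {
    d <- dplyr::bind_rows(d, dplyr::mutate(d, r_mm = -.data$r_mm))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$z_mm, .data$r_mm,
                                  fill = .data$amplitude_pa / 1e3)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "kPa") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (mm)", y = "r (mm)",
                  title = "Steady-state pressure amplitude")
}

#' @rdname autoplot-methods
#' @export
autoplot.fus_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$peak_kpa)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s [%s]", attr(object, "parameter"),
                              attr(object, "unit")),
                  y = "focal pressure (kPa)")
}

#' @rdname autoplot-methods
#' @export
autoplot.fus_fit <- function(object, ...) {
  xs <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  curve <- tibble(x = xs, y = predict(object, xs))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "swept value", y = "focal pressure (kPa)",
                  subtitle = sprintf("%s fit, R^2 = %.3f",
                                     object$model_form, object$r_squared))
}

#' Axial profile plot with an optional oracle overlay
#'
#' @param field A `fus_field`.
#' @param oracle Optional tibble with `z_mm` and `amplitude_pa` (e.g. from
#'   [oneil_axial()]) drawn as a dashed overlay.
#' @return A ggplot object.
#' @export
plot_axial_profile <- function(field, oracle = NULL) {
  p <- ggplot2::ggplot(axial_profile(field),
                       ggplot2::aes(.data$z_mm, .data$amplitude_pa / 1e3)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (mm)", y = "amplitude (kPa)")
  if (!is.null(oracle))
    p <- p + ggplot2::geom_line(data = oracle, linetype = "dashed",
                                colour = "firebrick")
  p
}
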