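# ggplot2 visualisations. Heights are plotted against sqrt(time), the natural
# scale on which Washburn kinetics are straight lines.

#' @exportS3Method ggplot2::autoplot
autoplot.imbibition_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_s", "height_m", "h_eq_m")],
    c("height_m", "h_eq_m"), names_to = "quantity", values_to = "height")
  df$quantity <- dplyr::recode(df$quantity, height_m = "meniscus height h",
                               h_eq_m = "equivalent height h_eq")
  ggplot2::ggplot(df, ggplot2::aes(sqrt(.data$time_s), 1000 * .data$height,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(sqrt(t) ~ (s^{1 / 2})), y = "height (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.washburn2d_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve[c("time_s", "h_lw_m", "h_eq_m")],
                            c("h_lw_m", "h_eq_m"),
                            names_to = "quantity", values_to = "height")
  df$quantity <- dplyr::recode(df$quantity, h_lw_m = "latewood meniscus",
                               h_eq_m = "equivalent height")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 3600, 1000 * .data$height,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "height (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.wi_reduced_kinetics <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$sqrt_time, 1000 * .data$h_eq_m)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = expression(sqrt(t) ~ (s^{1 / 2})),
                  y = expression(h[eq] ~ (mm))) +
    ggplot2::theme_minimal()
}

#' Plot a moisture-field snapshot
#'
#' Sharp-front saturation over one growth ring: height along the sample versus
#' lateral position across the earlywood.
#'
#' @param field A [moisture_field()] tibble.
#' @return A ggplot object.
#' @export
plot_moisture_field <- function(field) {
  ggplot2::ggplot(field, ggplot2::aes(1000 * .data$x_m, 1000 * .data$z_m,
                                      fill = .data$saturation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "lateral position (mm)", y = "height (mm)",
                  fill = "saturation",
                  subtitle = sprintf("t = %.0f s, latewood front at %.1f mm",
                                     attr(field, "time"), 1000 * attr(field, "h_lw"))) +
    ggplot2::theme_minimal()
}
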