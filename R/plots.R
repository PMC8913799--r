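# ggplot2 views of the result types

#' @export
autoplot.wavefield <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t_s * 1e3, y = .data$x_m * 1e3,
                                 fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = "lateral position (mm)",
                  fill = "v (a.u.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_velocity <- function(object, ...) {
  ggplot2::ggplot(object$arrivals,
                  ggplot2::aes(x = .data$x_m * 1e3, y = .data$t_arrival_s * 1e3)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$used), show.legend = FALSE) +
    ggplot2::geom_abline(intercept = object$intercept * 1e3,
                         slope = 1 / object$speed, colour = "firebrick") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::labs(x = "lateral position (mm)", y = "arrival time (ms)",
                  subtitle = sprintf("group velocity %.3g m/s (R² = %.3f)",
                                     object$speed, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.niti_fit <- function(object, n_curve = 61, ...) {
  grid <- seq(-90, 90, length.out = n_curve)
  curve <- predict(object, angles = grid)
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$angle_deg, y = .data$speed_m_s)) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scan angle (deg)", y = "Rayleigh speed (m/s)",
                  subtitle = sprintf(
                    "mu = %.3g kPa, G/mu = %.2f, delta/mu = %.2f, alpha = %.1f deg",
                    object$params$mu / 1e3, object$params$G / object$params$mu,
                    object$params$delta / object$params$mu, object$alpha)) +
    ggplot2::theme_minimal()
  if ("sd_m_s" %in% names(object$scan))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$speed_m_s - .data$sd_m_s,
                   ymax = .data$speed_m_s + .data$sd_m_s), width = 3)
  p
}

#' Plot a sliding-kernel speed map
#'
#' @param speed_map Output of [local_speed_map].
#' @return A ggplot object.
#' @export
plot_speed_map <- function(speed_map) {
  ggplot2::ggplot(speed_map,
                  ggplot2::aes(x = .data$center_x_m * 1e3, y = .data$row,
                               fill = .data$speed_m_s)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "speed (m/s)") +
    ggplot2::labs(x = "kernel center (mm)", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot a depth-averaged optic-axis map
#'
#' @param axis_map Output of [depth_averaged_axis] (needs `x`, `y` columns).
#' @return A ggplot object.
#' @export
plot_axis_map <- function(axis_map) {
  ggplot2::ggplot(axis_map,
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$psi_deg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b",
                                              "#f7f7f7", "#2166ac"),
                                  limits = c(-90, 90),
                                  name = "axis (deg)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
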