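#' Plot an inertial-delay surface
#'
#' Inertial delay against body mass on log-log axes, one line per movement
#' magnitude.
#'
#' @param object An `inertial_delay_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.inertial_delay_surface <- function(object, ...) {
  task <- attr(object, "task")
  mag_col <- if (task == "swing") "magnitude_deg" else "vnd"
  mag_lab <- if (task == "swing") "magnitude (deg)" else "perturbation (v_ND)"
  df <- dplyr::filter(tibble::as_tibble(object), .data$converged)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$mass_kg, y = 1e3 * .data$delay_s,
                               colour = factor(signif(.data[[mag_col]], 3)),
                               group = .data[[mag_col]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "body mass (kg)", y = "inertial delay (ms)",
                  colour = mag_lab,
                  title = sprintf("%s task", task)) +
    ggplot2::theme_minimal()
}

#' Plot per-magnitude power-law fits
#'
#' Coefficient (1-kg inertial delay) and exponent of the fitted power law
#' against movement magnitude, the quantitative content of the published
#' coefficient/exponent panels.
#'
#' @param object A `delay_scaling_fits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.delay_scaling_fits <- function(object, ...) {
  task <- attr(object, "task")
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  `coefficient (ms)` = 1e3 * .data$coefficient,
                  exponent = .data$exponent),
    c("coefficient (ms)", "exponent"),
    names_to = "panel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$magnitude, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = if (task == "swing") "movement magnitude (deg)"
                  else "perturbation (v_ND)",
                  y = NULL, title = sprintf("%s task power-law fits", task)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated movement
#'
#' Angle, angular velocity, and applied torque against time for one swing or
#' posture simulation.
#'
#' @param object A `swing_simulation` or `posture_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.swing_simulation <- function(object, ...) {
  plot_trace(object$trace, sprintf("swing task, M = %.3g kg, %.3g deg",
                                   object$params$body_mass, object$magnitude))
}

#' @rdname autoplot.swing_simulation
#' @exportS3Method ggplot2::autoplot
autoplot.posture_simulation <- function(object, ...) {
  if (!object$feasible) stop("nothing to plot: infeasible perturbation",
                             call. = FALSE)
  plot_trace(object$trace, sprintf("posture task, M = %.3g kg, v_nd = %.3g",
                                   object$params$body_mass, object$v_nd))
}

plot_trace <- function(trace, title) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(trace,
                     time_ms = 1e3 * .data$time,
                     `angle (deg)` = 180 / pi * .data$angle,
                     `angular velocity (rad/s)` = .data$angular_velocity,
                     `torque (N m)` = .data$torque),
    -"time_ms", names_to = "panel", values_to = "value")
  df$panel <- factor(df$panel, levels = c("angle (deg)",
                                          "angular velocity (rad/s)",
                                          "torque (N m)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo confidence intervals
#'
#' Fitted exponent with its 95% interval per magnitude.
#'
#' @param object A `monte_carlo_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.monte_carlo_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$magnitude, y = .data$exponent)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$exp_lo,
                                          ymax = .data$exp_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "magnitude", y = "delay exponent",
                  title = sprintf("%s task: Monte Carlo 95%% CI",
                                  object$task[1])) +
    ggplot2::theme_minimal()
}
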