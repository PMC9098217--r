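#' Diagnostic plots
#'
#' `autoplot()` methods give the standard diagnostic figure for each result
#' type: trajectory paths, contact-angle rose for ensembles, log-log MSD
#' with its power-law fit, CCDF tails, tangent autocorrelation with the
#' fitted exponential decay, sweep curves with the refined optimum, and the
#' trade-off parametric curve with its Pareto-optimal points highlighted.
#'
#' @param object A package result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name prw-autoplot
NULL

#' @rdname prw-autoplot
#' @export
autoplot.prw_trajectory <- function(object, ...) {
  g <- search_geometry(object$params)
  circ <- tibble::tibble(a = seq(0, 2 * pi, length.out = 181),
                         x = g$rtarg * cos(.data$a),
                         y = g$rtarg * sin(.data$a))
  ggplot2::ggplot(object$path, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       colour = "purple") +
    ggplot2::geom_path(colour = "grey30") +
    ggplot2::annotate("point", x = g$source_point[1], y = g$source_point[2],
                      colour = "darkgreen", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @rdname prw-autoplot
#' @export
autoplot.prw_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$theta_contact_rad)) +
    ggplot2::geom_histogram(breaks = seq(-pi, pi, length.out = 37),
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::labs(x = "contact angle (rad, source at 0)", y = NULL,
                  title = sprintf("p_contact = %.3f (n = %d)",
                                  object$p_contact, object$n))
}

#' @rdname prw-autoplot
#' @param fit Optional `prw_msd_fit` to overlay.
#' @export
autoplot.prw_msd <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (min)", y = "MSD (µm²)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(lag_min = object$lag_min,
                            msd_um2 = fit$gamma * object$lag_min^fit$alpha),
      colour = "red")
  }
  p
}

#' @rdname prw-autoplot
#' @export
autoplot.prw_ccdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$step_um, .data$ccdf)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step length (µm)", y = "CCDF")
}

#' @rdname prw-autoplot
#' @param v,dtheta Optional speed and angular diffusion for the exponential
#'   decay overlay `exp(-dtheta * s / v)`.
#' @export
autoplot.prw_acf <- function(object, v = NULL, dtheta = NULL, ...) {
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(.data$s_um, .data$mean_cos)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "arc separation s (µm)",
                  y = expression(paste("<cos ", theta, "(s)>")))
  if (!is.null(v) && !is.null(dtheta)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(s_um = object$bins$s_um,
                            mean_cos = exp(-dtheta * object$bins$s_um / v)),
      colour = "red")
  }
  p
}

#' @rdname prw-autoplot
#' @export
autoplot.prw_angle_density <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$theta_rad, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "contact angle (rad)", y = "density")
}

#' @rdname prw-autoplot
#' @param optimum Optional result of [optimal_dtheta()] to mark.
#' @export
autoplot.prw_sweep <- function(object, optimum = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$dtheta, .data$p_contact)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$p_contact - .data$se, ymax = .data$p_contact + .data$se)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(D[theta] ~ (min^-1)),
                  y = expression(p[contact]))
  if (!is.null(optimum)) {
    p <- p + ggplot2::geom_vline(xintercept = optimum$dtheta_star,
                                 colour = "red", linetype = 2)
  }
  p
}

#' @rdname prw-autoplot
#' @export
autoplot.prw_tradeoff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p_contact, .data$mod_fi)) +
    ggplot2::geom_path(colour = "grey50",
                       arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pareto)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = expression(p[contact]), y = "modified FI",
                  colour = "Pareto")
}
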