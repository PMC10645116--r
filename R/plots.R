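#' Plot an SPD series
#'
#' @param object An `spd_series`.
#' @param breakpoint Optional `bp_fit`; drawn as a dashed vertical line at
#'   the transition year.
#' @param ... Ignored.
#' @return A ggplot. The cal BP axis is reversed so time runs forward
#'   left to right (the present at the right edge).
#' @export
autoplot.spd_series <- function(object, breakpoint = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "cal BP", y = "summed probability",
      title = "Summed probability distribution"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint) && !is.na(breakpoint$break_cal_bp)) {
    p <- p + ggplot2::geom_vline(
      xintercept = breakpoint$break_cal_bp,
      linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Plot generational reproductive rates with growth waves shaded
#'
#' @param object A `growth_series`.
#' @param waves Optional `wave_set`; each wave is shaded.
#' @param ... Ignored.
#' @return A ggplot of R against calendar time (present on the right).
#' @export
autoplot.growth_series <- function(object, waves = NULL, ...) {
  df <- object[!is.na(object$R), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$R)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "cal BP", y = expression(R[t]),
      title = "Generational log reproductive rates"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(waves) && nrow(waves) > 0) {
    shade <- tibble::tibble(
      xmin = waves$end_cal_bp, xmax = waves$start_cal_bp
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25
    )
  }
  p
}

#' Plot a fitted reproduction curve over its wave's phase portrait
#'
#' @param object A `cc_fit`.
#' @param n_grid Curve resolution.
#' @param ... Ignored.
#' @return A ggplot of the observed (X, R) points with the fitted
#'   cooperation/competition curve.
#' @export
autoplot.cc_fit <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$X)
  pad <- diff(rng) * 0.05
  grid <- tibble::tibble(X = seq(rng[1] - pad, rng[2] + pad, length.out = n_grid))
  grid$R <- predict_R(object$params, grid$X)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$X, y = .data$R)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(
      x = expression(X[t] == log ~ SPD), y = expression(R[t]),
      title = sprintf(
        "R_m = %.3g, c = %.3g, w = %.3g (%s)",
        object$params$R_m, object$params$c, object$params$w, object$shape
      )
    ) +
    ggplot2::theme_minimal()
}

#' Phase-portrait plot
#'
#' @param growth A `growth_series` (or the tibble from [phase_portrait()]).
#' @return A ggplot of the (X, R) path in time order.
#' @export
plot_phase_portrait <- function(growth) {
  df <- if (inherits(growth, "growth_series")) phase_portrait(growth) else growth
  ggplot2::ggplot(df, ggplot2::aes(x = .data$X, y = .data$R)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(X[t] == log ~ SPD), y = expression(R[t]),
      title = "Phase portrait"
    ) +
    ggplot2::theme_minimal()
}
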