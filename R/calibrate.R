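#' Calibrate a single radiocarbon date
#'
#' Converts a conventional radiocarbon measurement into a calendar-year
#' probability density on a 1-year grid. At each integer calendar year theta
#' in the window the density is the Gaussian ordinate of the measured age at
#' the interpolated curve mean, with variance equal to the sum of the squared
#' lab error and squared curve error:
#' \deqn{d(\theta) = \phi\!\left(y_m;\ \mu(\theta),\ \sigma_m^2 +
#'   \sigma_c(\theta)^2\right).}
#'
#' With `normalize = TRUE` the ordinates are rescaled to sum to 1 over the
#' window. With `normalize = FALSE` (the "unnormalized" convention used for
#' SPD building) the raw ordinates are returned unrescaled, which avoids
#' spikes where the calibration curve is steep. Probability mass falling
#' outside the window is truncated, not reflected or redistributed.
#'
#' @param c14_age Conventional ¹⁴C age (yr BP); must lie within the ¹⁴C range
#'   spanned by the curve.
#' @param c14_error 1-sigma lab error (¹⁴C yr), positive.
#' @param curve A [`cal_curve`][read_cal_curve] object.
#' @param window Calendar window `c(min, max)` in cal BP; must lie within the
#'   curve's calendar support. Defaults to the past 15 000 years.
#' @param normalize Rescale the density to unit mass?
#' @return A `cal_density` tibble with columns `cal_bp` (consecutive integer
#'   years, ascending) and `density`.
#' @export
#' @examples
#' curve <- make_synthetic_curve(c(0, 3000))
#' d <- calibrate_date(1000, 10, curve, window = c(800, 1200))
#' d$cal_bp[which.max(d$density)] # mode at the true calendar age
calibrate_date <- function(c14_age, c14_error, curve,
                           window = c(0, 15000), normalize = TRUE) {
  stopifnot(
    is.numeric(c14_age), length(c14_age) == 1L, is.finite(c14_age),
    is.numeric(c14_error), length(c14_error) == 1L
  )
  if (c14_error <= 0) {
    stop("c14_error must be positive", call. = FALSE)
  }
  c14_rng <- range(curve$c14_age)
  if (c14_age < c14_rng[1] || c14_age > c14_rng[2]) {
    stop(
      "c14_age ", c14_age, " outside the ",
      "¹⁴C range [", round(c14_rng[1]), ", ", round(c14_rng[2]),
      "] spanned by curve '", attr(curve, "curve_name"), "'",
      call. = FALSE
    )
  }
  grid <- seq(ceiling(window[1]), floor(window[2]))
  knots <- curve_at(curve, grid)
  dens <- calib_density(c14_age, c14_error, knots$c14_age, knots$sigma)
  total <- sum(dens)
  if (total == 0) {
    warning("date ", c14_age, " ± ", c14_error,
      " has zero density over the window; returning zeros",
      call. = FALSE
    )
  } else if (normalize) {
    dens <- dens / total
  }
  out <- tibble::tibble(cal_bp = grid, density = dens)
  class(out) <- c("cal_density", class(out))
  attr(out, "normalized") <- normalize
  out
}

# Gaussian ordinate of the measurement at the curve mean; combined variance.
calib_density <- function(c14_age, c14_error, mu, sigma) {
  stats::dnorm(c14_age, mean = mu, sd = sqrt(c14_error^2 + sigma^2))
}
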