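#' Define a synthetic radiocarbon scenario
#'
#' A scenario bundles everything needed to generate a radiocarbon dataset
#' with the statistical structure the SPD analysis assumes: a population
#' trajectory governed by the cooperation/competition map, switched through
#' one or more parameter regimes ("epochs") to create abrupt demographic
#' transitions; calendar years of dated material drawn with probability
#' proportional to population size; and measured ¹⁴C ages forward-modelled
#' through a calibration curve with combined curve + lab Gaussian noise.
#'
#' Epochs run forward in time starting at the old end of the window; their
#' total length must cover the window. The true regime-switch years are
#' available from [scenario_truth()] for recovery tests.
#'
#' @param epochs Data frame with columns `duration` (generations) and
#'   `R_m`, `c`, `w` (one [cc_params()] regime per row), in forward-time
#'   order.
#' @param x0 Initial population size.
#' @param n_dates Number of radiocarbon dates to sample.
#' @param curve A [`cal_curve`][make_synthetic_curve]; the window must lie
#'   within its calendar support.
#' @param window Calendar window `c(min, max)` cal BP.
#' @param noise_sd Per-generation lognormal process noise (log scale).
#' @param lab_error 1-sigma lab error attached to every date (¹⁴C yr).
#' @param gen_width Generation length in years (default 30).
#' @param seed Integer seed making the whole scenario reproducible.
#' @return A `cc_scenario` object.
#' @export
#' @examples
#' curve <- make_synthetic_curve(c(0, 4000))
#' sc <- cc_scenario(
#'   epochs = data.frame(
#'     duration = c(50, 50),
#'     R_m = c(0.3, 1.2), c = c(0.03, 0.004), w = c(0, 0.8)
#'   ),
#'   x0 = 10, n_dates = 500, curve = curve, window = c(500, 3500), seed = 1
#' )
cc_scenario <- function(epochs, x0, n_dates, curve, window,
                        noise_sd = 0, lab_error = 25, gen_width = 30,
                        seed = 1L) {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(
    all(c("duration", "R_m", "c", "w") %in% names(epochs)),
    nrow(epochs) >= 1L, all(epochs$duration >= 1),
    n_dates >= 1, x0 > 0, lab_error >= 0,
    inherits(curve, "cal_curve"), length(window) == 2L
  )
  window <- sort(window)
  if (window[1] < min(curve$cal_bp) || window[2] > max(curve$cal_bp)) {
    stop("scenario window outside the calendar support of the curve",
      call. = FALSE
    )
  }
  span <- window[2] - window[1]
  if (sum(epochs$duration) * gen_width < span) {
    stop(
      "epochs cover ", sum(epochs$duration) * gen_width,
      " yr but the window spans ", span, " yr",
      call. = FALSE
    )
  }
  structure(
    list(
      epochs = epochs, x0 = x0, n_dates = n_dates, curve = curve,
      window = window, noise_sd = noise_sd, lab_error = lab_error,
      gen_width = gen_width, seed = as.integer(seed)
    ),
    class = "cc_scenario"
  )
}

#' Reference demographic-transition scenario
#'
#' The package's canonical synthetic study conditions: a Holocene-scale
#' window (1000-9000 cal BP), a population held at a low Ricker equilibrium
#' (`R_m = 0.3`, `c = 0.03`, size ~10) that switches at 4980 cal BP to a
#' cooperation/competition regime (`R_m = 2`, `c = 0.004`, `w = 0.8`) whose
#' upper equilibrium (~500) it reaches within about two generations — an
#' abrupt, roughly 50-fold expansion. Dates (default 5000) carry a 25 ¹⁴C-yr
#' lab error and are forward-modelled through a wiggly synthetic curve
#' (amplitude 20, period 500 yr, sigma 10); process noise is 0.05 per
#' generation on the log scale.
#'
#' @param seed Integer seed.
#' @param n_dates Number of dates to sample.
#' @return A [cc_scenario()].
#' @export
demo_scenario <- function(seed = 1L, n_dates = 5000) {
  curve <- make_synthetic_curve(c(0, 15000),
    slope = 1, wiggle_amp = 20,
    wiggle_period = 500, sigma = 10
  )
  cc_scenario(
    epochs = data.frame(
      duration = c(134, 134),
      R_m = c(0.3, 2), c = c(0.03, 0.004), w = c(0, 0.8)
    ),
    x0 = 10, n_dates = n_dates, curve = curve, window = c(1000, 9000),
    noise_sd = 0.05, lab_error = 25, seed = seed
  )
}

#' Ground truth of a scenario
#'
#' The parameter regime changes between two generation points, 30 years
#' apart; the population can first respond at the earlier (younger) of the
#' two. `switch_cal_bp` therefore timestamps each switch at the first
#' generation governed by the new regime — the first calendar year at
#' which the series level can actually shift, and the year a change-point
#' estimator is asked to recover.
#'
#' @param spec A [cc_scenario()].
#' @return A list with `switch_cal_bp` (calendar years of the regime
#'   switches, one fewer than epochs), the epoch parameter table, and the
#'   seed; serialize with [jsonlite::write_json()] for test harnesses.
#' @export
scenario_truth <- function(spec) {
  stopifnot(inherits(spec, "cc_scenario"))
  bounds <- spec$window[2] -
    (cumsum(spec$epochs$duration) + 1L) * spec$gen_width
  list(
    switch_cal_bp = utils::head(bounds, -1),
    epochs = as.data.frame(spec$epochs),
    window = spec$window,
    gen_width = spec$gen_width,
    seed = spec$seed
  )
}

#' Simulate the annual population curve of a scenario
#'
#' Runs the cooperation/competition map through the scenario's epochs
#' (each epoch continuing from the previous epoch's final size) and
#' linearly interpolates the generational sizes onto the annual calendar
#' grid of the window. Deterministic given the scenario seed. Extinction
#' (underflow) is flagged and the curve continues at the floor.
#'
#' @param spec A [cc_scenario()].
#' @return A tibble with `cal_bp` (ascending) and `size`;
#'   `attr(, "extinct")` flags underflow.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "cc_scenario"))
  set.seed(spec$seed)
  floor_val <- 1e-12
  n_gen_total <- ceiling((spec$window[2] - spec$window[1]) / spec$gen_width)
  sizes <- numeric(0)
  x <- spec$x0
  extinct <- FALSE
  for (e in seq_len(nrow(spec$epochs))) {
    par <- cc_params(spec$epochs$R_m[e], spec$epochs$c[e], spec$epochs$w[e])
    traj <- cc_simulate(par, x,
      n_gen = spec$epochs$duration[e],
      noise_sd = spec$noise_sd, floor = floor_val
    )
    if (isTRUE(attr(traj, "extinct"))) {
      extinct <- TRUE
      pad <- spec$epochs$duration[e] + 1L - nrow(traj)
      traj <- rbind(traj, tibble::tibble(
        generation = seq_len(pad), size = floor_val
      ))
    }
    # first entry duplicates the previous epoch's final size
    sizes <- c(sizes, if (e == 1) traj$size else traj$size[-1])
    x <- max(traj$size[nrow(traj)], floor_val)
  }
  sizes <- sizes[seq_len(n_gen_total + 1L)]
  gen_cal_bp <- spec$window[2] - (seq_along(sizes) - 1L) * spec$gen_width
  grid <- seq(spec$window[1], spec$window[2])
  annual <- stats::approx(gen_cal_bp, sizes, xout = grid, rule = 2)$y
  out <- tibble::tibble(cal_bp = grid, size = annual)
  attr(out, "extinct") <- extinct
  out
}

#' Sample radiocarbon dates from a population curve
#'
#' Draws `n_dates` calendar years with probability proportional to
#' population size — the core assumption behind SPD-based demography (more
#' people leave more datable material) — and forward-models each through
#' the scenario's calibration curve: the measured ¹⁴C age is the curve
#' mean at the sampled year plus Gaussian noise with variance
#' `lab_error^2 + curve_sigma^2`.
#'
#' @param population Annual population tibble from [simulate_population()]
#'   (columns `cal_bp`, `size`), non-negative and not all zero.
#' @param spec The [cc_scenario()] providing curve, lab error, count and
#'   seed.
#' @return A tibble of dates with columns `lab_id`, `c14_age`, `c14_error`,
#'   `curve_id`, `true_cal_bp` — the same dialect [build_spd()] consumes,
#'   plus the true calendar year for diagnostics.
#' @export
sample_dates <- function(population, spec) {
  stopifnot(
    inherits(spec, "cc_scenario"),
    is.data.frame(population),
    all(c("cal_bp", "size") %in% names(population))
  )
  if (any(population$size < 0) || all(population$size == 0)) {
    stop("population curve must be non-negative and not all zero",
      call. = FALSE
    )
  }
  set.seed(spec$seed + 1L)
  n <- spec$n_dates
  years <- sample(population$cal_bp, n, replace = TRUE, prob = population$size)
  knots <- curve_at(spec$curve, years)
  meas_sd <- sqrt(spec$lab_error^2 + knots$sigma^2)
  tibble::tibble(
    lab_id = sprintf("SYN-%05d", seq_len(n)),
    c14_age = knots$c14_age + stats::rnorm(n, 0, meas_sd),
    c14_error = spec$lab_error,
    curve_id = attr(spec$curve, "curve_name"),
    true_cal_bp = years
  )
}
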