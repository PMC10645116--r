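#' Generational log reproductive rates
#'
#' Converts a generational SPD series into the phase-space variables of
#' population dynamic analysis: `X = log(SPD)` (log relative population
#' size) and the per-generation log reproductive rate
#' `R[t] = X[t+1] - X[t]`, taken forward in time (decreasing cal BP).
#' Constant `R` over a stretch means exponential growth; `R` increasing
#' with `X` is the hyper-exponential signature of cooperation-driven
#' (Allee-type) growth.
#'
#' Bins whose value falls below `floor` are clamped to the floor before
#' taking logs and flagged; waves that touch a flagged bin are discarded by
#' [segment_waves()] since their rates are artefacts of the clamp.
#'
#' @param series A `gen_series` from [to_generations()] (any data frame with
#'   `bin_start_cal_bp` and `value` works).
#' @param floor Positive clamp applied before the log (default 1e-12).
#' @return A `growth_series` tibble, one row per generation in forward-time
#'   order, with columns `t` (bin start, cal BP), `value`, `X`, `R`
#'   (`NA` in the last row: there are `n - 1` rates for `n` generations)
#'   and `floored`.
#' @export
#' @examples
#' gen <- tibble::tibble(bin_start_cal_bp = c(900, 870, 840), value = c(10, 20, 5))
#' reproductive_rates(gen)$R # log(2), log(0.25), NA
reproductive_rates <- function(series, floor = 1e-12) {
  stopifnot(
    is.data.frame(series),
    all(c("bin_start_cal_bp", "value") %in% names(series)),
    floor > 0
  )
  if (nrow(series) < 2L) {
    stop("need at least 2 generational bins to compute rates", call. = FALSE)
  }
  ord <- order(series$bin_start_cal_bp, decreasing = TRUE) # forward in time
  value <- series$value[ord]
  floored <- value < floor
  if (all(floored)) {
    stop("all generational bins fall below the floor (", floor, ")",
      call. = FALSE
    )
  }
  X <- log(pmax(value, floor))
  out <- tibble::tibble(
    t = series$bin_start_cal_bp[ord],
    value = value,
    X = X,
    R = c(diff(X), NA_real_),
    floored = floored
  )
  class(out) <- c("growth_series", class(out))
  attr(out, "bin_width") <- attr(series, "bin_width") %||% 30L
  attr(out, "floor") <- floor
  out
}

#' Segment waves of uninterrupted population growth
#'
#' Splits a growth series into its maximal runs of consecutive generations
#' with `R > tolerance` — the "waves" of demographic expansion that the
#' cooperation/competition model is fitted to. Runs are maximal (not
#' extendable in either direction); waves with fewer than `min_points`
#' (X, R) pairs are returned but flagged unfittable, since the 3-parameter
#' model needs at least 4 points for a residual degree of freedom. Waves
#' touching a floored (near-zero) bin are dropped.
#'
#' @param growth A `growth_series` from [reproductive_rates()].
#' @param min_points Minimum (X, R) pairs for a wave to be fittable.
#' @param tolerance Growth-rate threshold; the default 0 demands strictly
#'   positive growth at every step. A small negative tolerance admits
#'   single near-zero dips.
#' @return A `wave_set` tibble, one row per wave, with `start_index` /
#'   `end_index` (positions of the first and last growth step in the
#'   forward-time series), `n_points`, `duration` (years: steps × bin
#'   width), `start_cal_bp`, `end_cal_bp`, `fittable`, and a `points`
#'   list-column of `(t, X, R)` tibbles.
#' @export
segment_waves <- function(growth, min_points = 4, tolerance = 0) {
  stopifnot(inherits(growth, "growth_series"), nrow(growth) >= 1L)
  width <- attr(growth, "bin_width")
  n_steps <- nrow(growth) - 1L
  R <- growth$R[seq_len(n_steps)]
  good <- !is.na(R) & R > tolerance
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  waves <- tibble::tibble(start_index = starts[keep], end_index = ends[keep])
  if (nrow(waves) > 0) {
    # a wave spanning steps i..j involves bins i..j+1
    touches_floor <- vapply(
      seq_len(nrow(waves)),
      function(k) any(growth$floored[waves$start_index[k]:(waves$end_index[k] + 1L)]),
      logical(1)
    )
    waves <- waves[!touches_floor, ]
  }
  out <- waves |>
    dplyr::mutate(
      wave = dplyr::row_number(),
      n_points = .data$end_index - .data$start_index + 1L,
      duration = .data$n_points * width,
      start_cal_bp = growth$t[.data$start_index],
      end_cal_bp = growth$t[.data$end_index + 1L],
      fittable = .data$n_points >= min_points,
      points = purrr::map2(
        .data$start_index, .data$end_index,
        function(a, b) growth[a:b, c("t", "X", "R")]
      )
    ) |>
    dplyr::relocate("wave")
  class(out) <- c("wave_set", class(out))
  attr(out, "bin_width") <- width
  attr(out, "tolerance") <- tolerance
  attr(out, "min_points") <- min_points
  out
}

#' Summarise wave durations
#'
#' @param waves A `wave_set` from [segment_waves()].
#' @param bin_width Histogram bin width in years (default 100).
#' @return A list with `mean_duration` (years), `n_waves`, and `histogram`
#'   (a tibble of `bin_start`, `bin_end`, `count`, bins closed on the left).
#' @export
wave_duration_stats <- function(waves, bin_width = 100) {
  stopifnot(is.data.frame(waves))
  if (nrow(waves) == 0L) {
    stop("no waves to summarise", call. = FALSE)
  }
  d <- waves$duration
  breaks <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  counts <- vapply(
    seq_len(length(breaks) - 1L),
    function(i) sum(d >= breaks[i] & d < breaks[i + 1]),
    integer(1)
  )
  structure(
    list(
      mean_duration = mean(d),
      n_waves = length(d),
      histogram = tibble::tibble(
        bin_start = breaks[-length(breaks)],
        bin_end = breaks[-1],
        count = counts
      )
    ),
    class = "wave_duration_stats"
  )
}

#' @export
print.wave_duration_stats <- function(x, ...) {
  cat("<wave_duration_stats> ", x$n_waves, " waves, mean duration ",
    round(x$mean_duration, 1), " yr\n",
    sep = ""
  )
  print(x$histogram, ...)
  invisible(x)
}

#' Phase portrait of a growth series
#'
#' Returns the (X, R) pairs of a growth series in temporal order — the
#' phase-space path used to diagnose density dependence. A horizontal band
#' indicates exponential growth; a humped path (R rising then falling with
#' X) is the joint signature of cooperation at low population size and
#' competition at high size.
#'
#' @param growth A `growth_series` from [reproductive_rates()].
#' @return A tibble of `t`, `X`, `R` in forward-time order, one row per
#'   growth step (the trailing generation, which has no rate, is dropped).
#' @export
phase_portrait <- function(growth) {
  stopifnot(inherits(growth, "growth_series"), nrow(growth) >= 1L)
  out <- growth[seq_len(max(nrow(growth) - 1L, 0L)), c("t", "X", "R")]
  tibble::as_tibble(out)
}
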