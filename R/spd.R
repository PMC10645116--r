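new_spd_series <- function(cal_bp, value, n_dates, normalized,
                           smoothing_window = 0, trim_bounds = NULL) {
  out <- tibble::tibble(cal_bp = cal_bp, value = value)
  class(out) <- c("spd_series", class(out))
  attr(out, "n_dates") <- n_dates
  attr(out, "normalized") <- normalized
  attr(out, "smoothing_window") <- smoothing_window
  attr(out, "trim_bounds") <- trim_bounds
  out
}

#' @export
print.spd_series <- function(x, ...) {
  cat(
    "<spd_series> ", nrow(x), " years (", min(x$cal_bp), "-", max(x$cal_bp),
    " cal BP), ", attr(x, "n_dates"), " dates, ",
    if (attr(x, "normalized")) "normalized" else "unnormalized",
    if (attr(x, "smoothing_window") > 0) {
      paste0(", ", attr(x, "smoothing_window"), "-yr rolling mean")
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  NextMethod()
}

#' Build a summed probability distribution (SPD)
#'
#' Sums the calibrated calendar-year densities of a set of radiocarbon dates
#' pointwise over a common annual grid. The SPD is the standard relative
#' proxy for past population size: more dated material per calendar year is
#' read as more people. By default the per-date densities are *not*
#' rescaled to unit mass ("unnormalized" SPD), so steep stretches of the
#' calibration curve do not produce artificial spikes.
#'
#' @param dates Data frame of radiocarbon dates with columns `c14_age`,
#'   `c14_error`, and (when `curves` is a registry) `curve_id`; extra columns
#'   such as `lab_id` or `region` are ignored.
#' @param curves A single [`cal_curve`][read_cal_curve] used for every date,
#'   or a named list of curves matched against `curve_id`.
#' @param window Calendar window `c(min, max)` in cal BP.
#' @param normalize Normalize each date's density to unit mass before
#'   summing?
#' @return An `spd_series` tibble with columns `cal_bp` and `value`
#'   (ascending cal BP; forward in time means reading it bottom-up), with
#'   the number of contributing dates in `attr(, "n_dates")`.
#' @export
#' @examples
#' curve <- make_synthetic_curve(c(0, 3000))
#' dates <- data.frame(c14_age = c(900, 1100), c14_error = 25)
#' spd <- build_spd(dates, curve, window = c(500, 1500))
build_spd <- function(dates, curves, window = c(0, 15000), normalize = FALSE) {
  dates <- as.data.frame(dates)
  if (nrow(dates) == 0L) {
    stop("no dates to sum: empty date table", call. = FALSE)
  }
  stopifnot(all(c("c14_age", "c14_error") %in% names(dates)))
  ids <- if ("curve_id" %in% names(dates)) {
    as.character(dates$curve_id)
  } else {
    rep("curve", nrow(dates))
  }
  grid <- seq(ceiling(window[1]), floor(window[2]))
  total <- numeric(length(grid))
  for (id in unique(ids)) {
    curve <- resolve_curve(curves, id)
    knots <- curve_at(curve, grid)
    c14_rng <- range(curve$c14_age)
    sel <- which(ids == id)
    for (i in sel) {
      age <- dates$c14_age[i]
      err <- dates$c14_error[i]
      if (!is.finite(age) || age < c14_rng[1] || age > c14_rng[2]) {
        stop("date ", i, " (", age, " BP) outside the ¹⁴C range of curve '",
          id, "'",
          call. = FALSE
        )
      }
      if (!is.finite(err) || err <= 0) {
        stop("date ", i, " has non-positive c14_error", call. = FALSE)
      }
      dens <- calib_density(age, err, knots$c14_age, knots$sigma)
      if (normalize) {
        s <- sum(dens)
        if (s > 0) dens <- dens / s
      }
      total <- total + dens
    }
  }
  new_spd_series(grid, total, n_dates = nrow(dates), normalized = normalize)
}

#' Smooth an SPD with a centered rolling mean
#'
#' Applies a centered moving average to damp year-to-year calibration noise
#' before breakpoint detection and generational binning. Even window widths
#' are rounded up to the next odd width so the window centres exactly on
#' each year. Edge years where the full window does not fit carry no value
#' and are dropped (they are meant to be trimmed anyway).
#'
#' @param spd An `spd_series`.
#' @param window Window width in years (default 200).
#' @return A shorter `spd_series` with `attr(, "smoothing_window")` set.
#' @export
rolling_smooth <- function(spd, window = 200) {
  stopifnot(inherits(spd, "spd_series"))
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  n <- nrow(spd)
  if (w > n) {
    stop("smoothing window (", w, ") exceeds series length (", n, ")",
      call. = FALSE
    )
  }
  sm <- as.numeric(stats::filter(spd$value, rep(1 / w, w), sides = 2))
  keep <- !is.na(sm)
  new_spd_series(
    spd$cal_bp[keep], sm[keep],
    n_dates = attr(spd, "n_dates"),
    normalized = attr(spd, "normalized"),
    smoothing_window = window,
    trim_bounds = attr(spd, "trim_bounds")
  )
}

#' Trim the low-density edges of an SPD
#'
#' Removes the leading and trailing stretches of a series where the SPD is
#' essentially zero because no dated material exists, which would otherwise
#' read as spurious population crashes at the window edges. Either explicit
#' calendar bounds are applied, or (`bounds = NULL`, the "auto" policy) all
#' years before the first and after the last value exceeding
#' `eps * max(value)` are dropped.
#'
#' @param spd An `spd_series`.
#' @param bounds Optional explicit `c(min, max)` cal BP bounds.
#' @param eps Relative floor for the auto policy (default 1e-6).
#' @return A contiguous `spd_series` with `attr(, "trim_bounds")` recording
#'   the applied bounds.
#' @export
trim_edges <- function(spd, bounds = NULL, eps = 1e-6) {
  stopifnot(inherits(spd, "spd_series"))
  if (is.null(bounds)) {
    floor_val <- eps * max(spd$value)
    idx <- which(spd$value > floor_val)
    if (length(idx) == 0L) {
      stop("auto trim removed the entire series (all values at the floor)",
        call. = FALSE
      )
    }
    keep <- seq(min(idx), max(idx))
  } else {
    stopifnot(length(bounds) == 2L)
    keep <- which(spd$cal_bp >= min(bounds) & spd$cal_bp <= max(bounds))
    if (length(keep) == 0L) {
      stop("explicit trim bounds exclude the entire series", call. = FALSE)
    }
  }
  new_spd_series(
    spd$cal_bp[keep], spd$value[keep],
    n_dates = attr(spd, "n_dates"),
    normalized = attr(spd, "normalized"),
    smoothing_window = attr(spd, "smoothing_window"),
    trim_bounds = range(spd$cal_bp[keep])
  )
}

#' Aggregate an annual SPD to generational time steps
#'
#' Sums annual SPD values in consecutive fixed-width bins, proceeding from
#' the anchor (by default the oldest year of the series) toward the present.
#' The default width of 30 years is the human generation length the growth
#' models are specified on; summing captures the generational population
#' trend while averaging over intra-generational variability. A trailing
#' partial bin is dropped, never zero-padded (padding would fabricate a
#' population crash).
#'
#' @param spd An `spd_series`.
#' @param width Bin width in years (default 30).
#' @param anchor Calendar year (cal BP) of the oldest year of the first bin;
#'   defaults to the oldest year present.
#' @return A `gen_series` tibble with columns `bin_start_cal_bp` (the oldest
#'   year of each bin) and `value`, ordered forward in time (decreasing
#'   cal BP).
#' @export
to_generations <- function(spd, width = 30, anchor = NULL) {
  stopifnot(inherits(spd, "spd_series"), width >= 1)
  width <- as.integer(width)
  if (is.null(anchor)) anchor <- max(spd$cal_bp)
  if (anchor > max(spd$cal_bp) || anchor < min(spd$cal_bp)) {
    stop("anchor ", anchor, " cal BP lies outside the series", call. = FALSE)
  }
  # forward in time: decreasing cal BP from the anchor
  years <- anchor - seq(0, anchor - min(spd$cal_bp))
  n_bins <- length(years) %/% width
  if (n_bins < 2L) {
    stop("fewer than 2 full ", width, "-yr bins; growth rates need at least 2",
      call. = FALSE
    )
  }
  vals <- spd$value[match(years, spd$cal_bp)]
  used <- vals[seq_len(n_bins * width)]
  value <- as.numeric(tapply(used, rep(seq_len(n_bins), each = width), sum))
  out <- tibble::tibble(
    bin_start_cal_bp = anchor - (seq_len(n_bins) - 1L) * width,
    value = value
  )
  class(out) <- c("gen_series", class(out))
  attr(out, "bin_width") <- width
  attr(out, "normalized") <- attr(spd, "normalized")
  attr(out, "n_dates") <- attr(spd, "n_dates")
  out
}

#' @export
print.gen_series <- function(x, ...) {
  cat(
    "<gen_series> ", nrow(x), " bins of ", attr(x, "bin_width"),
    " yr, ", max(x$bin_start_cal_bp), " -> ",
    min(x$bin_start_cal_bp), " cal BP (forward in time)\n",
    sep = ""
  )
  NextMethod()
}
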