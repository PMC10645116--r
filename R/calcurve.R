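#' Read an IntCal-style calibration curve file
#'
#' Parses the standard IntCal curve dialect: delimited text (tab, comma or
#' whitespace) with at least three numeric columns — calendar age (cal BP),
#' conventional radiocarbon age (¹⁴C yr BP), and the 1-sigma curve error
#' (¹⁴C yr). Lines starting with `#` and non-numeric header lines are
#' skipped; columns beyond the third are ignored.
#'
#' @param path Path to the curve file.
#' @param name Curve identifier (e.g. `"intcal20"`); stored as an attribute
#'   and matched against the `curve_id` column of date tables.
#' @return A `cal_curve` tibble with columns `cal_bp`, `c14_age`, `sigma`,
#'   sorted by ascending `cal_bp`. Linear interpolation between knots is the
#'   defined behaviour at non-knot years.
#' @export
#' @examples
#' f <- tempfile(fileext = ".14c")
#' writeLines(c("# toy curve", "0,0,10", "100,105,10", "200,195,10"), f)
#' read_cal_curve(f, "toy")
read_cal_curve <- function(path, name) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("calibration curve file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (all(is.na(vals[seq_len(min(3L, length(vals)))]))) next # header text
    if (length(fields) < 3L || anyNA(vals[1:3])) {
      stop("malformed curve row at line ", i, ": ", lines[i], call. = FALSE)
    }
    rows[[i]] <- vals[1:3]
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L) {
    stop("calibration curve needs at least 2 knots: ", path, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  new_cal_curve(m[, 1], m[, 2], m[, 3], name = name)
}

#' Construct a calibration curve from vectors
#'
#' @param cal_bp Calendar ages (cal BP, 0 = AD 1950).
#' @param c14_age Conventional ¹⁴C age at each calendar age.
#' @param sigma 1-sigma curve error, recycled if scalar; must be positive.
#' @param name Curve identifier.
#' @return A `cal_curve` tibble sorted by ascending `cal_bp`.
#' @export
new_cal_curve <- function(cal_bp, c14_age, sigma, name = "curve") {
  sigma <- rep_len(sigma, length(cal_bp))
  stopifnot(length(c14_age) == length(cal_bp))
  if (length(cal_bp) < 2L) {
    stop("calibration curve needs at least 2 knots", call. = FALSE)
  }
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]
  if (anyDuplicated(cal_bp)) {
    stop("calendar grid of curve '", name, "' has duplicated cal BP values",
      call. = FALSE
    )
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("curve '", name, "' has non-positive or non-finite sigma", call. = FALSE)
  }
  out <- tibble::tibble(cal_bp = cal_bp, c14_age = c14_age[ord], sigma = sigma[ord])
  class(out) <- c("cal_curve", class(out))
  attr(out, "curve_name") <- name
  out
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(
    "<cal_curve> ", attr(x, "curve_name"), ": ", nrow(x), " knots, ",
    min(x$cal_bp), "-", max(x$cal_bp), " cal BP\n",
    sep = ""
  )
  NextMethod()
}

# Linear interpolation of curve mean and error onto arbitrary calendar ages.
# Errors outside the calendar support (no extrapolation is defined).
curve_at <- function(curve, cal_bp) {
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1] | cal_bp > rng[2])) {
    stop(
      "requested calendar years outside curve '", attr(curve, "curve_name"),
      "' support [", rng[1], ", ", rng[2], "] cal BP",
      call. = FALSE
    )
  }
  tibble::tibble(
    cal_bp = cal_bp,
    c14_age = stats::approx(curve$cal_bp, curve$c14_age, xout = cal_bp)$y,
    sigma = stats::approx(curve$cal_bp, curve$sigma, xout = cal_bp)$y
  )
}

#' Generate a synthetic calibration curve
#'
#' Builds a linear calendar-to-¹⁴C mapping with an optional sinusoidal wiggle,
#' useful for forward-modelling radiocarbon samples in simulations. With
#' `wiggle_amp = 0` the curve maps calendar years to ¹⁴C years one-to-one
#' (slope 1), so calibrated densities centre on the true calendar age.
#'
#' @param span Calendar range `c(min, max)` in cal BP.
#' @param slope ¹⁴C years per calendar year.
#' @param wiggle_amp Amplitude of the sinusoidal wiggle (¹⁴C yr).
#' @param wiggle_period Wiggle period (calendar yr).
#' @param sigma Constant 1-sigma curve error (¹⁴C yr); must be positive.
#' @param name Curve identifier.
#' @param step Knot spacing in calendar years.
#' @return A `cal_curve` tibble.
#' @export
make_synthetic_curve <- function(span = c(0, 15000), slope = 1,
                                 wiggle_amp = 0, wiggle_period = 500,
                                 sigma = 10, name = "synthetic", step = 1) {
  stopifnot(length(span) == 2L, span[2] > span[1], sigma > 0)
  cal_bp <- seq(span[1], span[2], by = step)
  c14 <- slope * cal_bp + wiggle_amp * sin(2 * pi * cal_bp / wiggle_period)
  new_cal_curve(cal_bp, c14, sigma, name = name)
}

# Resolve a curve registry: a single cal_curve, or a named list of them.
resolve_curve <- function(curves, curve_id) {
  if (inherits(curves, "cal_curve")) {
    return(curves)
  }
  if (is.list(curves) && curve_id %in% names(curves)) {
    return(curves[[curve_id]])
  }
  stop("no calibration curve registered for curve_id '", curve_id, "'",
    call. = FALSE
  )
}
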