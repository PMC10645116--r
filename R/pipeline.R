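#' Pipeline configuration
#'
#' Collects every tunable of the dates-to-fits pipeline in one validated
#' object. The defaults reproduce the standard analysis settings: an
#' analysis window covering the past 15 000 years, unnormalized SPDs, a
#' 200-year rolling average, 30-year generational bins, auto edge
#' trimming, a mean-shift breakpoint with 15% trimming and a permutation
#' significance test, strictly positive growth waves with at least 4
#' points, and a constrained nonlinear least-squares model fit.
#'
#' @param window Calendar window `c(min, max)` cal BP.
#' @param normalize Normalize per-date densities before summing?
#' @param smooth_window Rolling-average width in years.
#' @param gen_width Generation length in years.
#' @param trim_bounds Optional explicit trim bounds (cal BP); `NULL` = auto.
#' @param trim_eps Relative floor for auto trimming.
#' @param bp_model Breakpoint regression: `"mean_shift"` or `"trend_shift"`.
#' @param bp_on Run the breakpoint search on the `"annual"` smoothed SPD
#'   (default, matching how transition dates are usually read off SPD
#'   plots) or on the `"generational"` bins.
#' @param trim_frac Minimum segment fraction for the breakpoint search.
#' @param sig_method Breakpoint significance: `"permutation"` or
#'   `"asymptotic"`.
#' @param n_perm Permutations for the significance test.
#' @param wave_tolerance Growth threshold for wave segmentation.
#' @param min_points Minimum (X, R) pairs per fittable wave.
#' @param fit_method `"nls"` or `"linear"`.
#' @param constrain Enforce `c, w >= 0` in wave fits.
#' @param growth_floor Clamp for near-zero generational bins before logs.
#' @param seed Integer seed used for the pipeline's stochastic stages
#'   (permutation test).
#' @return A `run_config` list; round-trips losslessly through
#'   [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(window = c(0, 15000), normalize = FALSE,
                       smooth_window = 200, gen_width = 30,
                       trim_bounds = NULL, trim_eps = 1e-6,
                       bp_model = "mean_shift", bp_on = "annual",
                       trim_frac = 0.15,
                       sig_method = "permutation", n_perm = 199,
                       wave_tolerance = 0, min_points = 4,
                       fit_method = "nls", constrain = TRUE,
                       growth_floor = 1e-12, seed = 1L) {
  cfg <- list(
    window = as.numeric(window), normalize = isTRUE(normalize),
    smooth_window = as.numeric(smooth_window),
    gen_width = as.integer(gen_width),
    trim_bounds = if (is.null(trim_bounds)) NULL else as.numeric(trim_bounds),
    trim_eps = as.numeric(trim_eps),
    bp_model = match.arg(bp_model, c("mean_shift", "trend_shift")),
    bp_on = match.arg(bp_on, c("annual", "generational")),
    trim_frac = as.numeric(trim_frac),
    sig_method = match.arg(sig_method, c("permutation", "asymptotic")),
    n_perm = as.integer(n_perm),
    wave_tolerance = as.numeric(wave_tolerance),
    min_points = as.integer(min_points),
    fit_method = match.arg(fit_method, c("nls", "linear")),
    constrain = isTRUE(constrain),
    growth_floor = as.numeric(growth_floor),
    seed = as.integer(seed)
  )
  stopifnot(
    length(cfg$window) == 2L, cfg$window[2] > cfg$window[1],
    cfg$smooth_window >= 1, cfg$gen_width >= 1,
    cfg$trim_frac > 0, cfg$trim_frac < 0.5,
    cfg$n_perm >= 99, cfg$min_points >= 4, cfg$growth_floor > 0
  )
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a pipeline configuration file
#'
#' Configurations serialize to a flat YAML mapping; reading applies
#' [run_config()] validation, so the round trip is lossless for valid
#' configurations.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Read a radiocarbon dates table
#'
#' Reads the dates CSV dialect: columns `lab_id`, `c14_age`, `c14_error`,
#' `curve_id`, and optionally `region`; extra columns are kept.
#'
#' @param path CSV file path.
#' @return A tibble of dates.
#' @export
read_dates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c14_age", "c14_error")
  if (!all(need %in% names(df))) {
    stop("dates file must have columns c14_age and c14_error", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a radiocarbon dates table
#'
#' @param dates Data frame of dates.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_dates <- function(dates, path) {
  utils::write.csv(as.data.frame(dates), path, row.names = FALSE)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message("[paleowave:", stage, "] ", ...)
}

#' Run the full demographic-transition analysis for one region
#'
#' Orchestrates the pipeline: calibrate and sum dates into an SPD, smooth
#' and trim it, detect the major demographic transition, aggregate to
#' generational bins, compute log reproductive rates, segment growth
#' waves, and fit the cooperation/competition model to each fittable wave.
#' Each stage logs one line (sizes in/out, warnings); the run is
#' deterministic given the dates, curves and configuration.
#'
#' @param dates Data frame of dates (see [read_dates()]).
#' @param curves A `cal_curve` or named list of curves.
#' @param config A [run_config()].
#' @param region Optional region label carried into the report.
#' @param quiet Suppress stage logging?
#' @return A `region_report` list with elements `region`, `n_dates`,
#'   `config`, `spd` (trimmed smoothed series), `breakpoint` (`bp_fit`),
#'   `p_value`, `generations`, `growth`, `waves` (with fits appended),
#'   `duration_stats` (`NULL` when no waves). Serialize with
#'   [report_json()].
#' @export
run_region <- function(dates, curves, config = run_config(), region = NULL,
                       quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_fn <- if (quiet) function(...) invisible() else stage_log
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", region %||% "region", "/", stage, "] ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  spd <- wrap("spd", build_spd(dates, curves,
    window = config$window,
    normalize = config$normalize
  ))
  log_fn("spd", nrow(dates), " dates -> ", nrow(spd), " annual values")
  spd_sm <- wrap("smooth", rolling_smooth(spd, window = config$smooth_window))
  spd_trim <- wrap("trim", trim_edges(spd_sm,
    bounds = config$trim_bounds,
    eps = config$trim_eps
  ))
  log_fn(
    "trim", "kept ", nrow(spd_trim), "/", nrow(spd_sm), " years (",
    max(spd_trim$cal_bp), "-", min(spd_trim$cal_bp), " cal BP)"
  )
  gen <- wrap("generations", to_generations(spd_trim, width = config$gen_width))
  log_fn("generations", nrow(gen), " bins of ", config$gen_width, " yr")
  bp_series <- if (config$bp_on == "annual") spd_trim else gen
  bp <- wrap("breakpoint", fit_single_breakpoint(bp_series,
    model = config$bp_model, trim_frac = config$trim_frac
  ))
  p_value <- wrap("significance", breakpoint_significance(bp,
    method = config$sig_method, n_perm = config$n_perm, seed = config$seed
  ))
  log_fn(
    "breakpoint", "shift at ", bp$break_cal_bp, " cal BP (sup-F = ",
    signif(bp$sup_f, 4), ", p = ", signif(p_value, 3), ")"
  )
  growth <- wrap("growth", reproductive_rates(gen, floor = config$growth_floor))
  if (any(growth$floored)) {
    log_fn("growth", sum(growth$floored), " bins at the floor (flagged)")
  }
  waves <- wrap("waves", segment_waves(growth,
    min_points = config$min_points,
    tolerance = config$wave_tolerance
  ))
  log_fn(
    "waves", nrow(waves), " waves (", sum(waves$fittable), " fittable, ",
    sum(!waves$fittable), " too short)"
  )
  waves <- wrap("fits", fit_waves(waves,
    method = config$fit_method,
    constrain = config$constrain
  ))
  stats <- if (nrow(waves) > 0) wave_duration_stats(waves) else NULL
  if (!is.null(stats)) {
    log_fn("fits", "mean wave duration ", round(stats$mean_duration), " yr")
  }
  structure(
    list(
      region = region %||% "unnamed",
      n_dates = nrow(dates),
      config = config,
      spd = spd_trim,
      breakpoint = bp,
      p_value = p_value,
      generations = gen,
      growth = growth,
      waves = waves,
      duration_stats = stats
    ),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report> ", x$region, ": ", x$n_dates, " dates\n",
    "  transition at ", x$breakpoint$break_cal_bp, " cal BP (p = ",
    signif(x$p_value, 3), ")\n",
    "  ", nrow(x$waves), " growth waves",
    if (!is.null(x$duration_stats)) {
      paste0(", mean duration ", round(x$duration_stats$mean_duration), " yr")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Serialize a region report to JSON
#'
#' Produces a deterministic JSON document (fixed precision, no list-column
#' payloads beyond the per-wave fit table) embedding the fully resolved
#' configuration for provenance.
#'
#' @param report A `region_report`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "region_report"))
  wv <- report$waves
  wave_table <- if (nrow(wv) > 0) {
    as.data.frame(wv[, setdiff(names(wv), c("points", "fit"))])
  } else {
    list()
  }
  doc <- list(
    region = report$region,
    n_dates = report$n_dates,
    config = unclass(report$config),
    breakpoint = list(
      break_cal_bp = report$breakpoint$break_cal_bp,
      break_index = report$breakpoint$break_index,
      sup_f = report$breakpoint$sup_f,
      p_value = report$p_value,
      model = report$breakpoint$model,
      seg1 = as.list(report$breakpoint$seg1_coef),
      seg2 = as.list(report$breakpoint$seg2_coef),
      no_structural_change = report$breakpoint$no_structural_change
    ),
    spd = list(
      cal_bp = report$spd$cal_bp,
      value = report$spd$value
    ),
    waves = wave_table,
    mean_wave_duration = if (!is.null(report$duration_stats)) {
      report$duration_stats$mean_duration
    } else {
      NULL
    }
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(10), null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
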