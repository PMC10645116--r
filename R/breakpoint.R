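# Segment-wise RSS for every admissible single split, via prefix sums.
# y is in forward-time order; model is "mean_shift" (segment means) or
# "trend_shift" (segment intercept + slope on the time index).
# Returns list(rss_split = vector over splits, cand = candidate last-index
# of segment 1, rss_null, p = params per segment).
split_rss <- function(y, model = c("mean_shift", "trend_shift"),
                      trim_frac = 0.15) {
  model <- match.arg(model)
  n <- length(y)
  p <- if (model == "mean_shift") 1L else 2L
  h <- max(ceiling(trim_frac * n), p)
  cand <- seq.int(h, n - h)
  cand <- cand[cand >= p & (n - cand) >= p]
  if (length(cand) == 0L) {
    stop("no admissible split points: series too short for trim_frac = ",
      trim_frac,
      call. = FALSE
    )
  }
  t <- seq_len(n)
  # zero-prefixed cumulative sums so segment sums are S[b + 1] - S[a]
  Sy <- c(0, cumsum(y))
  Syy <- c(0, cumsum(y^2))
  St <- c(0, cumsum(t))
  Stt <- c(0, cumsum(t^2))
  Sty <- c(0, cumsum(t * y))
  seg_rss <- function(a, b) {
    # closed-form least-squares RSS on y[a..b] (vectorized over a, b)
    m <- b - a + 1
    sy <- Sy[b + 1] - Sy[a]
    syy <- Syy[b + 1] - Syy[a]
    rss <- syy - sy^2 / m
    if (model == "trend_shift") {
      st <- St[b + 1] - St[a]
      stt <- Stt[b + 1] - Stt[a]
      sty <- Sty[b + 1] - Sty[a]
      sxx <- stt - st^2 / m
      sxy <- sty - st * sy / m
      rss <- rss - ifelse(sxx > 0, sxy^2 / sxx, 0)
    }
    pmax(rss, 0) # guard tiny negative round-off
  }
  rss1 <- seg_rss(rep(1L, length(cand)), cand)
  rss2 <- seg_rss(cand + 1L, rep(n, length(cand)))
  list(
    rss_split = rss1 + rss2,
    cand = cand,
    rss_null = seg_rss(1L, n),
    p = p
  )
}

seg_coef <- function(y, t, model) {
  if (model == "mean_shift" || length(y) < 2L || stats::var(t) == 0) {
    c(intercept = mean(y), slope = if (model == "trend_shift") 0 else NULL)
  } else {
    b <- stats::coef(stats::lm(y ~ t))
    c(intercept = unname(b[1]), slope = unname(b[2]))
  }
}

sup_f_from_rss <- function(rss_null, rss_split, n, p) {
  df2 <- n - 2 * p
  if (df2 <= 0) {
    return(rep(NA_real_, length(rss_split)))
  }
  num <- pmax(rss_null - rss_split, 0) / p
  den <- rss_split / df2
  ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
}

#' Detect a single structural breakpoint by least squares
#'
#' Finds the calendar position at which an SPD (or generational) series
#' shifts from one stable regression regime to another: every admissible
#' split point is tried, the chosen regression (segment means, or segment
#' intercept + slope on time) is fitted independently to the two segments,
#' and the split minimising the combined residual sum of squares is
#' returned. The pre-shift and post-shift levels are thus estimated
#' concurrently with the change point. The strength of the shift is
#' summarised by the sup-F statistic, the maximum over candidates of the
#' F ratio comparing the split fit against the single-regime fit.
#'
#' The search runs in forward-time order (decreasing cal BP), so
#' `break_cal_bp` is the first calendar year of the post-shift regime.
#'
#' @param series An `spd_series`, `gen_series`, or plain numeric vector
#'   (taken as already in forward-time order).
#' @param model `"mean_shift"` (default): a shift in the mean level, the
#'   natural reading of a step-like demographic transition.
#'   `"trend_shift"`: intercept and slope on time shift together.
#' @param trim_frac Minimum fraction of the series required on each side of
#'   the break (default 0.15, the usual structural-change convention).
#' @return A `bp_fit` object with elements `break_index` (last forward-time
#'   position of the pre-shift segment), `break_cal_bp`, `seg1_coef`,
#'   `seg2_coef`, `rss_split`, `rss_null`, `sup_f`, and
#'   `no_structural_change` (`TRUE` for a constant series, where
#'   `sup_f = 0`). Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' y <- c(rep(1, 20), rep(5, 20))
#' fit_single_breakpoint(y)$break_index # 20
fit_single_breakpoint <- function(series, model = c("mean_shift", "trend_shift"),
                                  trim_frac = 0.15) {
  model <- match.arg(model)
  fw <- forward_series(series)
  y <- fw$y
  n <- length(y)
  if (n < 4L) stop("series too short for breakpoint search", call. = FALSE)
  sr <- split_rss(y, model, trim_frac)
  best <- which.min(sr$rss_split)
  bi <- sr$cand[best]
  fvals <- sup_f_from_rss(sr$rss_null, sr$rss_split, n, sr$p)
  sup_f <- max(fvals)
  # constant (zero-variance) series: prefix-sum cancellation leaves RSS at
  # rounding-error scale, not exactly 0
  no_change <- sr$rss_null <= 1e-10 * sum(y^2)
  if (no_change) sup_f <- 0
  t <- seq_len(n)
  out <- structure(
    list(
      break_index = bi,
      break_cal_bp = if (!is.null(fw$cal_bp)) fw$cal_bp[bi + 1L] else NA_real_,
      model = model,
      trim_frac = trim_frac,
      seg1_coef = seg_coef(y[1:bi], t[1:bi], model),
      seg2_coef = seg_coef(y[(bi + 1):n], t[(bi + 1):n], model),
      rss_split = sr$rss_split[best],
      rss_null = sr$rss_null,
      sup_f = sup_f,
      no_structural_change = no_change,
      n = n,
      n_candidates = length(sr$cand),
      p = sr$p,
      y = y,
      cal_bp = fw$cal_bp
    ),
    class = "bp_fit"
  )
  out
}

# Put any supported series type into forward-time order (decreasing cal BP).
forward_series <- function(series) {
  if (inherits(series, "gen_series")) {
    ord <- order(series$bin_start_cal_bp, decreasing = TRUE)
    list(y = series$value[ord], cal_bp = series$bin_start_cal_bp[ord])
  } else if (inherits(series, "spd_series")) {
    ord <- order(series$cal_bp, decreasing = TRUE)
    list(y = series$value[ord], cal_bp = series$cal_bp[ord])
  } else if (is.numeric(series)) {
    list(y = as.numeric(series), cal_bp = NULL)
  } else {
    stop("unsupported series type for breakpoint search", call. = FALSE)
  }
}

#' @export
print.bp_fit <- function(x, ...) {
  cat("<bp_fit> ", x$model, " break at index ", x$break_index,
    if (!is.na(x$break_cal_bp)) paste0(" (", x$break_cal_bp, " cal BP)"),
    "\n  sup-F = ", signif(x$sup_f, 5),
    ", RSS ", signif(x$rss_null, 5), " -> ", signif(x$rss_split, 5),
    if (x$no_structural_change) "\n  [no structural change detected]",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Significance of a detected breakpoint
#'
#' Tests the null hypothesis of no structural change against a single
#' unknown shift point. The default permutation test re-draws the series by
#' permuting the residuals of the single-regime (null) fit, recomputes the
#' sup-F statistic for each permutation, and reports
#' `p = (1 + #permuted sup-F >= observed) / (1 + n_perm)`. The
#' `"asymptotic"` mode returns a Bonferroni-corrected pointwise F tail
#' bound over the admissible candidates — a conservative, clearly
#' approximate alternative when permutation is too slow.
#'
#' Note that permuting residuals treats them as exchangeable; on heavily
#' smoothed series the residuals are autocorrelated and the permutation p
#' is anti-conservative. Treat it as a ranking device, not a calibrated
#' error rate, on smoothed SPDs.
#'
#' @param fit A `bp_fit` from [fit_single_breakpoint()].
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation draw.
#' @return A single p-value.
#' @export
breakpoint_significance <- function(fit, method = c("permutation", "asymptotic"),
                                    n_perm = 199, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "bp_fit"))
  if (fit$sup_f == 0) {
    return(1)
  }
  y <- fit$y
  n <- fit$n
  if (method == "asymptotic") {
    df2 <- n - 2 * fit$p
    p_point <- stats::pf(fit$sup_f, fit$p, df2, lower.tail = FALSE)
    return(min(1, fit$n_candidates * p_point))
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n)
  fitted_null <- if (fit$model == "mean_shift") {
    rep(mean(y), n)
  } else {
    stats::fitted(stats::lm(y ~ t))
  }
  resid_null <- y - fitted_null
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    y_star <- fitted_null + sample(resid_null)
    sr <- split_rss(y_star, fit$model, fit$trim_frac)
    f_star <- max(sup_f_from_rss(sr$rss_null, sr$rss_split, n, sr$p))
    if (f_star >= fit$sup_f) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

#' @export
tidy.bp_fit <- function(x, ...) {
  seg <- function(coefs, segment) {
    tibble::tibble(
      segment = segment,
      term = names(coefs),
      estimate = unname(coefs)
    )
  }
  dplyr::bind_rows(seg(x$seg1_coef, "pre_shift"), seg(x$seg2_coef, "post_shift"))
}

#' @export
glance.bp_fit <- function(x, ...) {
  tibble::tibble(
    break_index = x$break_index,
    break_cal_bp = x$break_cal_bp,
    sup_f = x$sup_f,
    rss_null = x$rss_null,
    rss_split = x$rss_split,
    n = x$n,
    model = x$model,
    no_structural_change = x$no_structural_change
  )
}
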