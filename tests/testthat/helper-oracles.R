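# Independent brute-force oracles, deliberately naive: each re-derives a
# quantity the package computes by a cleverer route.

# identity-like curve on [0, span] with constant sigma
identity_curve <- function(span = 5000, sigma = 1e-6) {
  new_cal_curve(0:span, 0:span, sigma, name = "identity")
}

# direct evaluation of the calibrated density at each grid year
oracle_calibrate <- function(c14_age, c14_error, curve, window) {
  grid <- seq(window[1], window[2])
  mu <- approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  sg <- approx(curve$cal_bp, curve$sigma, xout = grid)$y
  dnorm(c14_age, mean = mu, sd = sqrt(c14_error^2 + sg^2))
}

# exhaustive single-breakpoint search by per-segment lm() calls
oracle_breakpoint <- function(y, model = "mean_shift", trim_frac = 0.15) {
  n <- length(y)
  p <- if (model == "mean_shift") 1L else 2L
  h <- max(ceiling(trim_frac * n), p)
  cand <- seq.int(h, n - h)
  cand <- cand[cand >= p & (n - cand) >= p]
  t <- seq_len(n)
  rss_seg <- function(idx) {
    if (model == "mean_shift") {
      sum((y[idx] - mean(y[idx]))^2)
    } else {
      sum(resid(lm(y[idx] ~ t[idx]))^2)
    }
  }
  rss <- vapply(cand, function(i) rss_seg(1:i) + rss_seg((i + 1):n), numeric(1))
  list(break_index = cand[which.min(rss)], rss = min(rss), cand = cand, all_rss = rss)
}

# bisection root finder for R(x) = R_m - c x - w / x on a bracket
oracle_bisect <- function(params, lo, hi, tol = 1e-12) {
  f <- function(x) params$R_m - params$c * x - params$w / x
  stopifnot(f(lo) * f(hi) <= 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# grid argmax of the reproduction curve
oracle_peak_grid <- function(params, lo = -10, hi = 10, step = 1e-4) {
  X <- seq(lo, hi, by = step)
  R <- params$R_m - params$c * exp(X) - params$w * exp(-X)
  X[which.max(R)]
}

# coarse (R_m, c, w) grid search around a fitted point: returns the best
# RSS on the grid, to certify the fit is no worse than any grid candidate
oracle_cc_grid_rss <- function(X, R, center, span = 2, n = 7) {
  gr <- function(v) seq(v / span, v * span, length.out = n)
  best <- Inf
  for (R_m in seq(center[1] / span, center[1] * span, length.out = n)) {
    for (cc in gr(max(center[2], 1e-8))) {
      for (w in gr(max(center[3], 1e-8))) {
        rss <- sum((R - (R_m - cc * exp(X) - w * exp(-X)))^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# deterministic trajectory of the cooperation/competition map
oracle_iterate <- function(params, x0, n_gen) {
  x <- numeric(n_gen + 1)
  x[1] <- x0
  for (t in 1:n_gen) {
    x[t + 1] <- x[t] * exp(params$R_m - params$c * x[t] - params$w / x[t])
  }
  x
}
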