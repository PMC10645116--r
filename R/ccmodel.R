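#' Cooperation/competition model parameters
#'
#' Parameter set of the discrete-time growth model
#' \deqn{R_t = R_m - c\,e^{X_t} - w\,e^{-X_t},}
#' a Ricker map augmented with a hyperbolic Allee (cooperation) term,
#' written on the log scale with `X = log(x)` and `R = log(x[t+1]/x[t])`.
#'
#' * `R_m` — log maximum reproductive rate per generation, attained when
#'   neither competition nor cooperation constraints bind.
#' * `c` — intensity of intra-population competition, per population-size
#'   unit: the larger `c`, the faster growth declines with size.
#' * `w` — intensity of cooperation, in population-size units: the larger
#'   `w`, the larger the population needed before growth picks up
#'   (positive density dependence at low size).
#'
#' `c` and `w` are scale-dependent: fitted to SPD values they are expressed
#' per SPD unit, so only comparisons on the same data scale are meaningful.
#'
#' @param R_m Finite log maximum reproductive rate.
#' @param c Competition intensity, `>= 0`.
#' @param w Cooperation intensity, `>= 0`.
#' @return A `cc_params` object (named list).
#' @export
#' @examples
#' p <- cc_params(R_m = 0.6, c = 0.01, w = 5)
#' predict_R(p, X = log(20))
cc_params <- function(R_m, c, w) {
  stopifnot(
    is.numeric(R_m), length(R_m) == 1L, is.finite(R_m),
    is.numeric(c), length(c) == 1L, is.finite(c), c >= 0,
    is.numeric(w), length(w) == 1L, is.finite(w), w >= 0
  )
  structure(list(R_m = R_m, c = c, w = w), class = "cc_params")
}

#' @export
print.cc_params <- function(x, ...) {
  cat("<cc_params> R_m = ", signif(x$R_m, 5), ", c = ", signif(x$c, 5),
    ", w = ", signif(x$w, 5), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predicted log reproductive rate
#'
#' Evaluates `R = R_m - c * exp(X) - w * exp(-X)` — the model's reproduction
#' curve — at log population size `X`. With both `c > 0` and `w > 0` the
#' curve is strictly concave and humped; with `w = 0` it reduces to the
#' (log) Ricker model, monotone decreasing in `X`.
#'
#' @param params A [cc_params()] object.
#' @param X Log population size(s); vectorized.
#' @return Numeric vector of predicted rates.
#' @export
predict_R <- function(params, X) {
  stopifnot(inherits(params, "cc_params"), all(is.finite(X)))
  params$R_m - params$c * exp(X) - params$w * exp(-X)
}

#' Simulate a population trajectory
#'
#' Iterates the map `x[t+1] = x[t] * r_m * exp(-c * x[t] - w / x[t])`,
#' optionally with multiplicative lognormal process noise
#' `exp(eps)`, `eps ~ N(0, noise_sd^2)`, applied each generation. If the
#' population underflows `floor` the trajectory is truncated there and
#' flagged extinct.
#'
#' @param params A [cc_params()] object.
#' @param x0 Initial population size, `> 0`.
#' @param n_gen Number of generations to iterate.
#' @param noise_sd Standard deviation of the per-generation log noise.
#' @param seed Optional integer seed (only consulted when `noise_sd > 0`).
#' @param floor Extinction floor.
#' @return A tibble with columns `generation` (0..n) and `size`;
#'   `attr(, "extinct")` flags underflow truncation.
#' @export
cc_simulate <- function(params, x0, n_gen, noise_sd = 0, seed = NULL,
                        floor = 1e-12) {
  stopifnot(inherits(params, "cc_params"), is.numeric(x0), length(x0) == 1L)
  if (!is.finite(x0) || x0 <= 0) {
    stop("initial size x0 must be positive", call. = FALSE)
  }
  if (noise_sd > 0 && !is.null(seed)) set.seed(seed)
  x <- numeric(n_gen + 1L)
  x[1] <- x0
  extinct <- FALSE
  last <- n_gen + 1L
  for (t in seq_len(n_gen)) {
    r <- exp(params$R_m - params$c * x[t] - params$w / x[t])
    xt1 <- x[t] * r
    if (noise_sd > 0) xt1 <- xt1 * exp(stats::rnorm(1, 0, noise_sd))
    if (!is.finite(xt1) || xt1 < floor) {
      extinct <- TRUE
      last <- t
      break
    }
    x[t + 1L] <- xt1
  }
  out <- tibble::tibble(
    generation = seq_len(last) - 1L,
    size = x[seq_len(last)]
  )
  attr(out, "extinct") <- extinct
  attr(out, "params") <- params
  out
}

#' Equilibria of the cooperation/competition map
#'
#' Population equilibria solve `R(x) = 0`, i.e. the quadratic
#' `c x^2 - R_m x + w = 0`. With `c, w > 0` and `R_m^2 >= 4 c w` there are
#' two positive roots: `x_lower`, the Allee threshold below which the
#' population declines to extinction, and `x_upper`, the carrying-capacity
#' equilibrium. Degenerate cases are handled analytically: pure Ricker
#' (`w = 0`) has the single equilibrium `R_m / c`; pure cooperation
#' (`c = 0`) has the single threshold `w / R_m`. Stability is read from the
#' map derivative: a root `x*` is stable when `|1 - c x* + w / x*| < 1`.
#'
#' @param params A [cc_params()] object.
#' @return A `cc_equilibria` list with `x_lower`, `x_upper`, `exists`
#'   (two positive roots, possibly coincident), `double_root`, and
#'   `stability` (named logical for each finite root).
#' @export
cc_equilibria <- function(params) {
  stopifnot(inherits(params, "cc_params"))
  R_m <- params$R_m
  cc <- params$c
  w <- params$w
  stab <- function(x) abs(1 - cc * x + w / x) < 1
  res <- list(
    x_lower = NA_real_, x_upper = NA_real_,
    exists = FALSE, double_root = FALSE,
    stability = c(lower = NA, upper = NA)
  )
  if (cc == 0 && w == 0) {
    # density-independent: no finite equilibrium (unless R_m = 0, where
    # every size is neutrally stationary; reported as non-existent too)
  } else if (w == 0) {
    if (R_m > 0) {
      res$x_upper <- R_m / cc
      res$stability["upper"] <- stab(res$x_upper)
    }
  } else if (cc == 0) {
    if (R_m > 0) {
      res$x_lower <- w / R_m
      res$stability["lower"] <- stab(res$x_lower)
    }
  } else {
    disc <- R_m^2 - 4 * cc * w
    if (R_m > 0 && disc >= 0) {
      # numerically stable quadratic roots
      q <- (R_m + sqrt(disc)) / 2
      roots <- sort(c(w / q, q / cc))
      res$x_lower <- roots[1]
      res$x_upper <- roots[2]
      res$exists <- TRUE
      res$double_root <- disc == 0
      res$stability <- c(lower = stab(roots[1]), upper = stab(roots[2]))
    }
  }
  structure(res, class = "cc_equilibria")
}

#' @export
print.cc_equilibria <- function(x, ...) {
  if (x$exists) {
    cat("<cc_equilibria> x_lower = ", signif(x$x_lower, 6),
      " (", if (isTRUE(x$stability["lower"])) "stable" else "unstable", "), ",
      "x_upper = ", signif(x$x_upper, 6),
      " (", if (isTRUE(x$stability["upper"])) "stable" else "unstable", ")",
      if (x$double_root) " [double root]", "\n",
      sep = ""
    )
  } else if (is.finite(x$x_upper) || is.finite(x$x_lower)) {
    cat("<cc_equilibria> single equilibrium at ",
      signif(if (is.finite(x$x_upper)) x$x_upper else x$x_lower, 6), "\n",
      sep = ""
    )
  } else {
    cat("<cc_equilibria> no positive equilibrium\n")
  }
  invisible(x)
}

#' Peak of the reproduction curve
#'
#' With `c, w > 0` the reproduction curve `R(X)` has a unique interior
#' maximum at `X_peak = log(w / c) / 2`, where
#' `R_peak = R_m - 2 * sqrt(c * w)`. The peak location marks the log
#' population size at which cooperation benefits are exhausted and
#' competition starts to dominate.
#'
#' @param params A [cc_params()] object with `c > 0` and `w > 0`.
#' @return Named list with `X_peak` and `R_peak`.
#' @export
cc_peak <- function(params) {
  stopifnot(inherits(params, "cc_params"))
  if (params$c <= 0 || params$w <= 0) {
    stop("reproduction curve has no interior maximum unless both c > 0 and w > 0",
      call. = FALSE
    )
  }
  list(
    X_peak = 0.5 * log(params$w / params$c),
    R_peak = params$R_m - 2 * sqrt(params$c * params$w)
  )
}
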