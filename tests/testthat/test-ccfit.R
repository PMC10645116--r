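wave_XR <- function(params, x0 = 12, n = 12) {
  x <- oracle_iterate(params, x0, n)
  tibble::tibble(X = log(x[-(n + 1)]), R = diff(log(x)))
}

test_that("noiseless model data are interpolated exactly", {
  truth <- cc_params(0.6, 0.01, 5)
  df <- wave_XR(truth)
  for (m in c("linear", "nls")) {
    fit <- fit_cc(df, method = m)
    expect_equal(fit$params$R_m, 0.6, tolerance = 1e-8)
    expect_equal(fit$params$c, 0.01, tolerance = 1e-8)
    expect_equal(fit$params$w, 5, tolerance = 1e-8)
    expect_lt(fit$rss, 1e-16)
    expect_equal(fit$shape, "humped")
  }
})

test_that("unconstrained linear and nls estimates agree to 1e-6", {
  set.seed(55)
  for (i in 1:10) {
    df <- wave_XR(cc_params(0.6, 0.01, 5))
    df$R <- df$R + rnorm(nrow(df), 0, 0.05)
    lin <- fit_cc(df, method = "linear", constrain = FALSE)
    nl <- fit_cc(df, method = "nls", constrain = FALSE)
    expect_equal(lin$estimate, nl$estimate, tolerance = 1e-6)
    expect_equal(lin$rss, nl$rss, tolerance = 1e-9)
  }
})

test_that("pure Ricker data drive w to the boundary without AIC penalty", {
  set.seed(66)
  ok_w0 <- 0
  ok_aic <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    p <- cc_params(0.5, 0.005, 0)
    x <- oracle_iterate(p, 8, 14)
    df <- tibble::tibble(X = log(x[-15]), R = diff(log(x)) + rnorm(14, 0, 0.02))
    fit <- fit_cc(df, method = "nls", constrain = TRUE)
    if (fit$params$w < 1e-6) ok_w0 <- ok_w0 + 1
    if (is.na(fit$delta_aic) || fit$delta_aic <= 2) ok_aic <- ok_aic + 1
  }
  expect_gte(ok_aic / n_rep, 0.9) # Ricker never worse by more than 2 AICc
  # under a true Ricker the constrained w sits on the boundary about half
  # the time (one-sided noise); demand a substantial fraction
  expect_gte(ok_w0 / n_rep, 0.3)
})

test_that("full fit never has larger RSS than the nested Ricker fit", {
  set.seed(77)
  for (i in 1:20) {
    x <- exp(runif(10, 1, 4))
    df <- tibble::tibble(X = log(x), R = rnorm(10, 0, 0.3))
    fit <- fit_cc(df, method = "nls")
    expect_lte(fit$rss, fit$nested_ricker$rss + 1e-10)
    fit_l <- fit_cc(df, method = "linear")
    expect_lte(fit_l$rss, fit_l$nested_ricker$rss + 1e-10)
    # no grid candidate around the fit beats the fitted RSS
    ctr <- pmax(abs(fit$estimate), 1e-6)
    expect_lte(fit$rss, oracle_cc_grid_rss(df$X, df$R, ctr) + 1e-10)
  }
})

test_that("constrained fits respect the bounds and flag degeneracy", {
  # R decreasing in X with upward curvature wants negative w
  df <- tibble::tibble(X = log(c(5, 10, 20, 40, 80)), R = c(0.9, 0.4, 0.25, 0.1, 0.0))
  fit <- fit_cc(df, method = "linear", constrain = TRUE)
  expect_gte(fit$params$c, 0)
  expect_gte(fit$params$w, 0)
  free <- fit_cc(df, method = "linear", constrain = FALSE)
  expect_lte(free$rss, fit$rss + 1e-12)
  expect_error(fit_cc(df[1:3, ]), "at least 4")
  expect_error(
    fit_cc(tibble::tibble(X = rep(2, 6), R = rnorm(6))),
    "distinct X"
  )
})

test_that("parameter recovery: median estimates within 10% at n = 12, sd 0.05", {
  set.seed(88)
  truth <- cc_params(0.6, 0.01, 5)
  n_rep <- 100
  est <- matrix(NA_real_, n_rep, 3)
  for (i in seq_len(n_rep)) {
    df <- wave_XR(truth)
    df$R <- df$R + rnorm(12, 0, 0.05)
    fit <- fit_cc(df, method = "nls")
    est[i, ] <- c(fit$params$R_m, fit$params$c, fit$params$w)
  }
  med <- apply(est, 2, median)
  expect_lt(abs(med[1] - 0.6) / 0.6, 0.10)
  expect_lt(abs(med[2] - 0.01) / 0.01, 0.10)
  expect_lt(abs(med[3] - 5) / 5, 0.10)
})

test_that("estimator bias is small at n = 30, sd 0.02", {
  set.seed(99)
  truth <- cc_params(0.6, 0.01, 5)
  x_grid <- seq(log(11), log(48), length.out = 30)
  n_rep <- 300
  est <- matrix(NA_real_, n_rep, 3)
  for (i in seq_len(n_rep)) {
    df <- tibble::tibble(
      X = x_grid,
      R = predict_R(truth, x_grid) + rnorm(30, 0, 0.02)
    )
    fit <- fit_cc(df, method = "linear")
    est[i, ] <- c(fit$params$R_m, fit$params$c, fit$params$w)
  }
  bias <- colMeans(est) - c(0.6, 0.01, 5)
  expect_lt(abs(bias[1]) / 0.6, 0.05)
  expect_lt(abs(bias[2]) / 0.01, 0.05)
  expect_lt(abs(bias[3]) / 5, 0.05)
})

test_that("broom-style accessors expose estimates and diagnostics", {
  truth <- cc_params(0.6, 0.01, 5)
  df <- wave_XR(truth)
  df$R <- df$R + rnorm(12, 0, 0.01)
  fit <- fit_cc(df)
  td <- tidy(fit)
  expect_equal(td$term, c("R_m", "c", "w"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$n, 12L)
  expect_gt(gl$r.squared, 0.5)
  au <- augment(fit)
  expect_equal(au$.resid, au$R - predict_R(fit$params, au$X))
})

test_that("fit_waves appends per-wave estimates and skips short waves", {
  truth <- cc_params(0.6, 0.01, 5)
  x <- oracle_iterate(truth, 12, 14)
  v <- c(x, x[15] * exp(cumsum(rnorm(3, -0.3, 0.01)))) # growth then decline
  set.seed(7)
  g <- reproductive_rates(tibble::tibble(
    bin_start_cal_bp = 3000 - 30 * (seq_along(v) - 1),
    value = v
  ))
  ws <- fit_waves(segment_waves(g))
  fitted <- ws[ws$fittable, ]
  expect_gte(nrow(fitted), 1)
  expect_equal(fitted$R_m[1], 0.6, tolerance = 1e-6)
  expect_equal(fitted$w[1], 5, tolerance = 1e-4)
  expect_s3_class(fitted$fit[[1]], "cc_fit")
})
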