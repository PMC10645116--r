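toy_dates <- function(n, span = c(600, 4400), seed = 1) {
  set.seed(seed)
  tibble::tibble(
    lab_id = paste0("D", seq_len(n)),
    c14_age = runif(n, span[1], span[2]),
    c14_error = runif(n, 15, 40),
    curve_id = "syn"
  )
}

test_that("SPD is the pointwise sum of per-date densities", {
  cv <- make_synthetic_curve(c(0, 5000), wiggle_amp = 15, sigma = 10, name = "syn")
  w <- c(200, 4800)
  d1 <- toy_dates(1)
  spd1 <- build_spd(d1, list(syn = cv), window = w)
  cal1 <- calibrate_date(d1$c14_age, d1$c14_error, cv, window = w, normalize = FALSE)
  expect_equal(spd1$value, cal1$density) # singleton sum
  expect_identical(attr(spd1, "n_dates"), 1L)

  # two identical dates: exactly twice the single-date density
  spd2 <- build_spd(d1[c(1, 1), ], list(syn = cv), window = w)
  expect_equal(spd2$value, 2 * spd1$value)

  # five random dates, normalized: mass 5 and loop-and-add oracle pointwise
  d5 <- toy_dates(5, seed = 3)
  spd5 <- build_spd(d5, list(syn = cv), window = w, normalize = TRUE)
  expect_equal(sum(spd5$value), 5, tolerance = 1e-4)
  acc <- numeric(nrow(spd5))
  for (i in 1:5) {
    di <- oracle_calibrate(d5$c14_age[i], d5$c14_error[i], cv, w)
    acc <- acc + di / sum(di)
  }
  expect_equal(spd5$value, acc, tolerance = 1e-12)
})

test_that("build_spd validates its inputs", {
  cv <- make_synthetic_curve(c(0, 5000), name = "syn")
  expect_error(build_spd(toy_dates(0), list(syn = cv)), "empty")
  d <- toy_dates(2)
  d$curve_id <- "mystery"
  expect_error(build_spd(d, list(syn = cv), window = c(0, 5000)), "mystery")
})

test_that("rolling mean is exact on constants, ramps, and a hand-computed case", {
  mk <- function(v) paleowave:::new_spd_series(seq_along(v), v, 1L, FALSE)
  expect_equal(rolling_smooth(mk(rep(2, 50)), 5)$value, rep(2, 46))
  ramp <- rolling_smooth(mk(1:50), 5)
  expect_equal(ramp$value, 3:48) # symmetric window leaves a line unchanged
  y <- c(4, 2, 9, 1, 3, 5, 8, 2, 6)
  sm <- rolling_smooth(mk(y), 3)
  expect_equal(sm$value, vapply(2:8, function(i) mean(y[(i - 1):(i + 1)]), 1))
  expect_error(rolling_smooth(mk(1:5), 7), "exceeds")
})

test_that("edge trimming drops only the low-density margins", {
  v <- c(rep(0, 300), runif(400, 0.5, 1), rep(0, 120))
  spd <- paleowave:::new_spd_series(1000 + seq_along(v) - 1, v, 1L, FALSE)
  tr <- trim_edges(spd)
  expect_equal(nrow(tr), 400)
  expect_equal(min(tr$cal_bp), 1300)
  # noisy near-zero tails: bounds equal first/last index above eps * max
  set.seed(9)
  v2 <- c(abs(rnorm(50, 0, 1e-9)), runif(200, 0.2, 1), abs(rnorm(30, 0, 1e-9)))
  spd2 <- paleowave:::new_spd_series(seq_along(v2), v2, 1L, FALSE)
  tr2 <- trim_edges(spd2, eps = 1e-6)
  idx <- which(v2 > 1e-6 * max(v2)) # linear-scan oracle
  expect_equal(range(tr2$cal_bp), range(idx))
  # explicit bounds: exact slice
  tr3 <- trim_edges(spd, bounds = c(1350, 1500))
  expect_equal(tr3$cal_bp, 1350:1500)
  expect_error(trim_edges(spd, bounds = c(5000, 6000)), "exclude")
  zero <- paleowave:::new_spd_series(1:10, rep(0, 10), 1L, FALSE)
  expect_error(trim_edges(zero), "entire series")
})

test_that("generational binning sums exact 30-yr blocks and drops partials", {
  mk <- function(v, start = 3000) {
    paleowave:::new_spd_series(start - rev(seq_along(v)) + 1, rev(v), 1L, FALSE)
  }
  # value 1 per year: every bin = 30
  g <- to_generations(mk(rep(1, 90)))
  expect_equal(g$value, rep(30, 3))
  expect_equal(g$bin_start_cal_bp, c(3000, 2970, 2940)) # forward in time
  # 90-yr ramp 1..90 forward in time: arithmetic-series bins
  g2 <- to_generations(mk(1:90))
  expect_equal(g2$value, c(sum(1:30), sum(31:60), sum(61:90)))
  # partial trailing bin dropped
  g3 <- to_generations(mk(rep(1, 95)))
  expect_equal(nrow(g3), 3L)
  expect_error(to_generations(mk(rep(1, 45))), "fewer than 2")
})

test_that("binning conserves mass over the binned span", {
  set.seed(11)
  v <- runif(400)
  spd <- paleowave:::new_spd_series(seq_along(v), v, 1L, FALSE)
  g <- to_generations(spd, width = 30)
  n_used <- nrow(g) * 30
  used_years <- max(spd$cal_bp) - seq_len(n_used) + 1
  expect_equal(sum(g$value), sum(v[spd$cal_bp %in% used_years]),
    tolerance = 1e-12
  )
})

test_that("duplicating every date doubles the SPD and leaves growth rates unchanged", {
  cv <- make_synthetic_curve(c(0, 5000), name = "syn")
  d <- toy_dates(12, span = c(1800, 3200), seed = 5)
  w <- c(200, 4800)
  one <- build_spd(d, list(syn = cv), window = w)
  two <- build_spd(d[rep(1:12, 2), ], list(syn = cv), window = w)
  expect_equal(two$value, 2 * one$value, tolerance = 1e-12)
  g1 <- reproductive_rates(to_generations(trim_edges(rolling_smooth(one))))
  g2 <- reproductive_rates(to_generations(trim_edges(rolling_smooth(two))))
  # invariance holds wherever the log is taken of real (unfloored) mass
  ok_bin <- !(g1$floored | g2$floored)
  ok_step <- ok_bin[-length(ok_bin)] & ok_bin[-1]
  expect_gt(sum(ok_step), 50)
  n <- nrow(g1)
  expect_equal(g2$R[-n][ok_step], g1$R[-n][ok_step], tolerance = 1e-10)
  expect_equal(g2$X[ok_bin] - g1$X[ok_bin],
    rep(log(2), sum(ok_bin)),
    tolerance = 1e-10
  )
})
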