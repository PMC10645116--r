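mk_gen <- function(v, start = 3000, width = 30) {
  g <- tibble::tibble(
    bin_start_cal_bp = start - (seq_along(v) - 1) * width,
    value = v
  )
  attr(g, "bin_width") <- width
  class(g) <- c("gen_series", class(g))
  g
}

test_that("reproductive rates are forward-time log first differences", {
  expect_equal(reproductive_rates(mk_gen(rep(4, 6)))$R, c(rep(0, 5), NA))
  # geometric growth: constant R = log(lambda)
  lam <- 1.17
  g <- reproductive_rates(mk_gen(10 * lam^(0:9)))
  expect_equal(g$R[1:9], rep(log(lam), 9))
  # hand oracle
  g2 <- reproductive_rates(mk_gen(c(10, 20, 5)))
  expect_equal(g2$R, c(log(2), log(0.25), NA))
  expect_equal(g2$X, log(c(10, 20, 5)))
  expect_equal(sum(!is.na(g2$R)), nrow(g2) - 1L)
})

test_that("near-zero bins are floored and flagged; all-floored errors", {
  g <- reproductive_rates(mk_gen(c(1, 0, 2)), floor = 1e-12)
  expect_equal(g$floored, c(FALSE, TRUE, FALSE))
  expect_equal(g$X[2], log(1e-12))
  expect_error(reproductive_rates(mk_gen(c(0, 0))), "below the floor")
})

test_that("waves are maximal positive-growth runs with exact bounds", {
  inc <- reproductive_rates(mk_gen(exp(seq(0, 2, length.out = 10))))
  w1 <- segment_waves(inc)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start_index, w1$end_index), c(1L, 9L))
  expect_equal(w1$duration, 9 * 30)

  dec <- reproductive_rates(mk_gen(exp(seq(2, 0, length.out = 10))))
  expect_equal(nrow(segment_waves(dec)), 0L)

  # hand-built: growth at steps 1-5 and 9-14, declines elsewhere
  r <- rep(-0.1, 16)
  r[1:5] <- 0.2
  r[9:14] <- 0.15
  v <- exp(cumsum(c(0, r)))
  ws <- segment_waves(reproductive_rates(mk_gen(v)))
  expect_equal(ws$start_index, c(1L, 9L))
  expect_equal(ws$end_index, c(5L, 14L))
  expect_equal(ws$fittable, c(TRUE, TRUE))
  expect_equal(ws$n_points, c(5L, 6L))
  # points carry the in-run (X, R) pairs
  expect_equal(ws$points[[1]]$R, r[1:5])
})

test_that("waves partition all positive steps and respect the tolerance", {
  set.seed(21)
  for (i in 1:10) {
    v <- exp(cumsum(rnorm(40, 0, 0.3)))
    g <- reproductive_rates(mk_gen(v))
    ws <- segment_waves(g, tolerance = 0)
    covered <- unlist(purrr::map2(ws$start_index, ws$end_index, seq))
    expect_equal(sort(covered), which(g$R[-nrow(g)] > 0)) # disjoint + exhaustive
    expect_equal(anyDuplicated(covered), 0L)
    # every wave duration is a multiple of the bin width
    expect_true(all(ws$duration %% 30 == 0))
  }
})

test_that("waves touching floored bins are discarded", {
  v <- c(1, 2, 4, 0, 3, 6, 12, 24)
  ws <- segment_waves(reproductive_rates(mk_gen(v)), min_points = 2)
  # run over the zero bin (R jumps up from the floor) must not survive
  expect_true(all(vapply(
    ws$points,
    function(p) all(is.finite(p$X) & p$X > log(1e-6)), logical(1)
  )))
})

test_that("scale invariance: rescaling bins shifts X but not R or waves", {
  set.seed(33)
  v <- exp(cumsum(rnorm(30, 0.05, 0.2)))
  a <- reproductive_rates(mk_gen(v))
  b <- reproductive_rates(mk_gen(1000 * v))
  expect_equal(a$R, b$R, tolerance = 1e-12)
  expect_equal(b$X - a$X, rep(log(1000), 30))
  wa <- segment_waves(a)
  wb <- segment_waves(b)
  expect_equal(wa$start_index, wb$start_index)
  expect_equal(wa$duration, wb$duration)
})

test_that("duration statistics summarise wave lengths", {
  one <- tibble::tibble(duration = 300)
  expect_equal(wave_duration_stats(one)$mean_duration, 300)
  two <- tibble::tibble(duration = c(300, 450))
  st <- wave_duration_stats(two)
  expect_equal(st$mean_duration, 375)
  expect_equal(st$n_waves, 2L)
  set.seed(4)
  d <- tibble::tibble(duration = 30 * sample(4:20, 50, replace = TRUE))
  st50 <- wave_duration_stats(d)
  expect_equal(st50$mean_duration, mean(d$duration))
  expect_equal(sum(st50$histogram$count), 50L)
  expect_error(wave_duration_stats(tibble::tibble(duration = numeric(0))), "no waves")
})

test_that("phase portraits preserve temporal order without mutating input", {
  g <- reproductive_rates(mk_gen(c(5, 10, 20, 10)))
  g_before <- g
  pp <- phase_portrait(g)
  expect_equal(nrow(pp), 3L)
  expect_equal(pp$X, g$X[1:3])
  expect_equal(pp$R, g$R[1:3])
  expect_identical(g, g_before)
  # exponential growth: horizontal line in phase space
  ppg <- phase_portrait(reproductive_rates(mk_gen(2 * 1.3^(0:8))))
  expect_equal(ppg$R, rep(log(1.3), 8))
})

test_that("cooperation-dominated dynamics show R rising with X below threshold", {
  p <- cc_params(R_m = 0.6, c = 0.01, w = 5)
  x <- oracle_iterate(p, 12, 12)
  g <- tibble::tibble(X = log(x[-13]), R = diff(log(x)))
  below <- g$X < cc_peak(p)$X_peak
  expect_gte(sum(below), 3)
  expect_gt(cor(g$X[below], g$R[below], method = "spearman"), 0)
  # empirical argmax of R sits within a grid step of the closed-form peak
  traj_peak <- g$X[which.max(g$R)]
  gap <- max(abs(diff(g$X)))
  expect_lt(abs(traj_peak - cc_peak(p)$X_peak), gap)
})
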