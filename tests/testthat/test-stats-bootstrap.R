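# Maximum-statistic bootstrap: degenerate inputs, enumeration oracles,
# quantile conventions, equivariance.

test_that("all-zero baselines give a zero null distribution", {
  base <- matrix(0, 3, 600)
  null <- bootstrap_max_null(base, frame_rate = 10, segment_length = 5,
                             n_boot = 500, seed = 1)
  expect_equal(null$samples, rep(0, 500))
  expect_equal(null$threshold, 0)
})

test_that("defaults produce a 10,000-sample distribution", {
  set.seed(1)
  base <- matrix(rnorm(2 * 480), 2) # 120 s at 4 Hz
  null <- bootstrap_max_null(base, frame_rate = 4, seed = 1)
  expect_length(null$samples, 10000)
  expect_equal(null$segment_length, 11)
  expect_equal(null$quantile_level, 0.95)
})

test_that("one-mouse bootstrap matches exhaustive enumeration of segment starts", {
  fs <- 20
  t <- (0:(120 * fs - 1)) / fs
  # deterministic quasi-periodic series whose 110 window maxima are distinct
  saw <- sin(2 * pi * t / 13) + 0.6 * sin(2 * pi * t / 7.3) + 0.2 * t / 120
  L <- 11 * fs

  # oracle: enumerate all whole-second starts 0..109 s
  enum <- vapply(0:109, function(s) max(saw[s * fs + 1:L]), 0)
  expect_length(enum, 110)
  expect_gt(length(unique(enum)), 10)

  null <- bootstrap_max_null(saw, frame_rate = fs, n_boot = 20000,
                             seed = 3, start_stride = 1)
  expect_equal(null$n_starts, 110)
  expect_true(all(null$samples %in% enum))
  # distributional match: uniform over the 110 enumerated maxima (DKW)
  ecdf_boot <- ecdf(null$samples)
  ecdf_enum <- ecdf(enum)
  expect_lt(max(abs(ecdf_boot(enum) - ecdf_enum(enum))), 0.02)
  # threshold sits at the enumeration's 95% order statistic (up to the
  # sampling noise of the empirical quantile, a couple of ranks)
  expect_true(null$threshold %in% enum)
  expect_true(null$threshold %in% sort(enum)[103:107])
})

test_that("two-mouse bootstrap matches enumeration over start pairs", {
  fs <- 10
  set.seed(8)
  b1 <- as.numeric(arima.sim(list(ar = 0.9), 120 * fs))
  b2 <- as.numeric(arima.sim(list(ar = 0.9), 120 * fs))
  L <- 11 * fs
  seg <- function(b, s) b[s * fs + 1:L]
  S1 <- t(vapply(0:109, function(s) seg(b1, s), numeric(L)))
  S2 <- t(vapply(0:109, function(s) seg(b2, s), numeric(L)))
  # oracle: all 110 x 110 start pairs
  enum <- numeric(110 * 110)
  k <- 0
  for (i in 1:110) {
    mx <- apply(sweep(S2, 2, S1[i, ], "+") / 2, 1, max)
    enum[k + 1:110] <- mx
    k <- k + 110
  }
  null <- bootstrap_max_null(rbind(b1, b2), frame_rate = fs, n_boot = 20000,
                             seed = 5, start_stride = 1)
  expect_lt(max(abs(ecdf(null$samples)(enum) - ecdf(enum)(enum))), 0.02)
  expect_lt(abs(mean(null$samples) - mean(enum)), 4 * sd(enum) / sqrt(20000))
})

test_that("threshold follows the inverse-CDF order statistic and is monotone", {
  set.seed(2)
  base <- matrix(rnorm(480), 1)
  null95 <- bootstrap_max_null(base, 4, n_boot = 1000, seed = 9,
                               quantile_level = 0.95)
  null99 <- bootstrap_max_null(base, 4, n_boot = 1000, seed = 9,
                               quantile_level = 0.99)
  expect_identical(null95$samples, null99$samples) # same draws, same seed
  expect_equal(null95$threshold, sort(null95$samples)[950])
  expect_equal(null99$threshold, sort(null99$samples)[990])
  expect_gte(null99$threshold, null95$threshold)
})

test_that("absolute mode dominates signed mode", {
  set.seed(6)
  base <- matrix(rnorm(2 * 480), 2)
  s <- bootstrap_max_null(base, 4, n_boot = 500, seed = 1, mode = "signed")
  a <- bootstrap_max_null(base, 4, n_boot = 500, seed = 1, mode = "absolute")
  expect_true(all(a$samples >= s$samples))
})

test_that("scale equivariance: inputs scaled by k scale thresholds, not decisions", {
  set.seed(11)
  base <- matrix(rnorm(3 * 480), 3)
  win <- matrix(rnorm(3 * 44) + 1.5, 3,
                dimnames = list(c("m1", "m2", "m3"), NULL))
  zero <- matrix(0, 3, 44, dimnames = dimnames(win))
  k <- 3.7
  time <- seq(-1, 10, length.out = 44)

  n1 <- bootstrap_max_null(base, 4, n_boot = 400, seed = 2)
  n2 <- bootstrap_max_null(k * base, 4, n_boot = 400, seed = 2)
  expect_equal(n2$threshold, k * n1$threshold)
  expect_equal(n2$samples, k * n1$samples)

  t1 <- paired_difference_traces(win, zero, time = time)
  t2 <- paired_difference_traces(k * win, zero, time = time)
  expect_equal(t2$mean, k * t1$mean)

  r1 <- detect_windows(t1, n1)
  r2 <- detect_windows(t2, n2)
  expect_equal(r1$intervals, r2$intervals) # same windows

  wm1 <- window_means(win, zero, time, c(0, 5))
  wm2 <- window_means(k * win, k * zero, time, c(0, 5))
  expect_equal(wm2$difference, k * wm1$difference)
  expect_equal(wilcoxon_signed_rank(wm2$a, wm2$b)$p.value,
               wilcoxon_signed_rank(wm1$a, wm1$b)$p.value)
})

test_that("degenerate inputs are rejected", {
  expect_error(bootstrap_max_null(matrix(1, 2, 10), 10, segment_length = 11),
               "shorter")
  base <- matrix(1, 2, 600); base[1, 5] <- NA
  expect_error(bootstrap_max_null(base, 10, segment_length = 5), "missing")
})
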