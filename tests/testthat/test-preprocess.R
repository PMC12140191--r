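# Preprocessing: gap interpolation, normalizations, derived signals,
# per-mouse averaging.

test_that("interpolation is a no-op at full confidence and linear in gaps", {
  v <- c(2, 7, 4, 9)
  out <- interpolate_low_confidence(v, rep(1, 4))
  expect_equal(out$values, v)
  expect_equal(out$n_replaced, 0)

  out <- interpolate_low_confidence(c(2, 100, 4), c(1, 0.1, 1))
  expect_equal(out$values, c(2, 3, 4))
  expect_equal(out$replaced_fraction, 1 / 3)

  # leading/trailing gaps hold the nearest valid value
  out <- interpolate_low_confidence(c(9, 5, 9), c(0, 1, 0))
  expect_equal(out$values, c(5, 5, 5))

  expect_error(interpolate_low_confidence(1:3, c(0, 0, 0)), "unusable")
})

test_that("interpolation error on a smooth signal stays within the curvature bound", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  clean <- sin(2 * pi * 1.5 * t)
  set.seed(4)
  conf <- rep(1, length(t))
  drop <- sample(2:(length(t) - 1), round(0.05 * length(t)))
  conf[drop] <- 0.2
  out <- interpolate_low_confidence(clean, conf)

  # independent oracle: explicit two-point linear interpolation per gap
  oracle <- clean
  good <- which(conf >= 0.9)
  for (i in setdiff(seq_along(t), good)) {
    lo <- max(good[good < i]); hi <- min(good[good > i])
    w <- (i - lo) / (hi - lo)
    oracle[i] <- (1 - w) * clean[lo] + w * clean[hi]
  }
  expect_equal(out$values, oracle)

  # max error of linear interpolation <= max|f''| h^2 / 8 over the widest gap
  gaps <- diff(good)
  h <- max(gaps) / fs
  bound <- (2 * pi * 1.5)^2 * h^2 / 8
  expect_lt(max(abs(out$values - clean)), bound + 1e-12)
})

test_that("both normalizations zero their window, are idempotent and shift-equivariant", {
  tl <- trial_timeline(2, 4, 1, 10)
  expect_equal(unclass(baseline_normalize(rep(3, 50), tl)), rep(0, 50),
               ignore_attr = TRUE)

  # linear ramp: closed-form expectation
  t <- (0:49) / 10
  a <- 1.7
  ramp <- a * t
  base_mean <- a * mean(t[t < 2])
  expect_equal(as.numeric(baseline_normalize(ramp, tl)), ramp - base_mean)
  pre_mean <- a * mean(t[t >= 3 & t < 4])
  expect_equal(as.numeric(prethreat_normalize(ramp, tl)), ramp - pre_mean)

  set.seed(2)
  for (k in 1:10) {
    v <- rnorm(50) * 10
    c0 <- rnorm(1) * 100
    for (f in list(baseline_normalize, prethreat_normalize)) {
      n1 <- f(v, tl)
      expect_equal(as.numeric(f(n1, tl)), as.numeric(n1)) # idempotent
      expect_equal(as.numeric(f(v + c0, tl)), as.numeric(n1)) # shift-equivariant
    }
  }

  # a signal equal to its own pre-threat mean is zero at threat onset
  v <- rep(5, 50)
  expect_equal(as.numeric(prethreat_normalize(v, tl))[41], 0)

  expect_error(baseline_normalize(rep(1, 10), tl), "baseline window")
})

test_that("pupil diameter is a symmetric absolute separation", {
  expect_equal(pupil_diameter(c(3, 3), c(7, 7)), c(4, 4))
  expect_equal(pupil_diameter(c(7, 7), c(3, 3)), c(4, 4)) # swap-invariant
  expect_equal(pupil_diameter(1:3, 1:3), rep(0, 3))
  # translation-invariant
  expect_equal(pupil_diameter(1:3 + 50, 4:6 + 50), pupil_diameter(1:3, 4:6))
  expect_error(pupil_diameter(1:3, 1:4), "length")
})

test_that("point speed is the displacement norm times the frame rate", {
  expect_equal(point_speed(rep(1, 5), rep(2, 5), 200), rep(0, 5))
  # uniform motion of 1 px/frame at 200 Hz
  expect_equal(point_speed(1:5, rep(0, 5), 200), rep(200, 5))
  # pure y motion
  expect_equal(point_speed(rep(0, 4), c(0, 2, 4, 6), 100), rep(200, 4))
  # translation-invariant
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(point_speed(x + 9, y - 4, 50), point_speed(x, y, 50))
  expect_error(point_speed(1, 1, 200), "2 frames")
})

test_that("per-mouse averaging respects exclusions and flags empty mice", {
  expect_equal(average_trials_per_mouse(rbind(rep(4, 3)))$mean, rep(4, 3))
  expect_equal(average_trials_per_mouse(rbind(rep(0, 4), rep(2, 4)))$mean,
               rep(1, 4))

  traces <- matrix(rep(1:5, each = 3), 5, 3, byrow = TRUE)
  out <- average_trials_per_mouse(traces, excluded = c(F, F, T, F, F))
  expect_equal(out$n_used, 4)
  expect_equal(out$n_total, 5)
  expect_equal(out$mean, rep(mean(c(1, 2, 4, 5)), 3))

  out <- average_trials_per_mouse(rbind(rep(1, 3)), excluded = TRUE)
  expect_true(out$missing)
  expect_null(out$mean)
})

test_that("deriving diameter commutes with normalization (linearity)", {
  tl <- trial_timeline(2, 4, 1, 10)
  set.seed(9)
  top <- rnorm(50); bottom <- top - 3 - abs(rnorm(50))
  d_then_n <- baseline_normalize(pupil_diameter(top, bottom), tl)
  n_then_d <- baseline_normalize(top - bottom, tl) # top > bottom throughout
  expect_equal(as.numeric(d_then_n), as.numeric(n_then_d))
})
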