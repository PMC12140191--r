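# Difference traces, window means, and the difference-of-differences
# contrast.

test_that("difference traces have the stated mean/SEM structure", {
  m <- rbind(m1 = rep(1, 5), m2 = rep(1, 5))
  expect_equal(paired_difference_traces(m, m)$mean, rep(0, 5))

  a <- rbind(m1 = rep(2, 5), m2 = rep(4, 5))
  b <- 0 * a
  tr <- paired_difference_traces(a, b)
  expect_equal(unname(tr$mean), rep(3, 5))
  expect_equal(unname(tr$sem), rep(1, 5)) # sd(c(2,4))/sqrt(2) = 1
  expect_equal(tr$n_mice, 2)
})

test_that("mice missing one condition are dropped and logged", {
  a <- rbind(m1 = rep(1, 4), m2 = rep(2, 4), m3 = rep(3, 4))
  b <- rbind(m1 = rep(0, 4), m3 = rep(0, 4))
  tr <- paired_difference_traces(a, b)
  expect_equal(tr$n_mice, 2)
  expect_setequal(tr$dropped_mice, "m2")
  expect_setequal(tr$mice, c("m1", "m3"))

  only_a <- rbind(mA = rep(1, 4))
  only_b <- rbind(mB = rep(1, 4))
  expect_error(paired_difference_traces(only_a, only_b), "no mice")
})

test_that("window means: constants, ramp midpoint, identical conditions", {
  time <- (-10:100) / 10 # exact tenths
  k <- length(time)
  a <- rbind(m1 = rep(7, k), m2 = rep(2, k))
  b <- 0 * a
  wm <- window_means(a, b, time, c(0, 5))
  expect_equal(wm$a, c(7, 2))
  expect_equal(wm$b, c(0, 0))

  ramp <- rbind(m1 = time)
  # symmetric window around t = 3: the mean is the midpoint value
  w <- c(2, 4 + 0.1) # half-open [2, 4.1) covers samples 2..4 inclusive
  expect_equal(window_means(ramp, 0 * ramp, time, w)$a, 3)

  same <- window_means(a, a, time, c(1, 2))
  expect_equal(same$a, same$b)
  expect_equal(same$difference, c(0, 0))

  expect_error(window_means(a, b, time, c(9, 20)), "outside")
})

test_that("identical experiments give a null difference-of-differences", {
  time <- seq(-1, 10, length.out = 100)
  set.seed(3)
  d <- matrix(rnorm(300), 3, dimnames = list(c("m1", "m2", "m3"), NULL))
  limb <- paired_difference_traces(d, 0 * d, time = time)
  block <- paired_difference_traces(d, 0 * d, time = time)
  base <- matrix(rnorm(3 * 600), 3, dimnames = list(rownames(d), NULL))
  out <- contrast_of_contrasts(limb, block, base, base, frame_rate = 10,
                               n_boot = 300, seed = 2)
  expect_equal(unname(out$trace$mean), rep(0, 100))
  expect_equal(out$null$threshold, 0) # second-order baselines cancel
  expect_equal(nrow(out$report$intervals), 0)
})

test_that("a limb-only second-order effect yields a late window", {
  fs <- 20
  time <- (0:(11 * fs - 1) - fs) / fs
  mice <- paste0("m", 1:6)
  set.seed(14)
  eff <- ifelse(time >= 1 & time < 7, 2.5, 0)
  noise <- function() {
    t(vapply(mice, function(m) rnorm(length(time), sd = 0.4),
             numeric(length(time))))
  }
  limb_d <- noise() + rep(eff, each = 6); rownames(limb_d) <- mice
  block_d <- noise(); rownames(block_d) <- mice
  limb <- paired_difference_traces(limb_d, 0 * limb_d, time = time)
  block <- paired_difference_traces(block_d, 0 * block_d, time = time)
  lb <- matrix(rnorm(6 * 60 * fs, sd = 0.4), 6, dimnames = list(mice, NULL))
  bb <- matrix(rnorm(6 * 60 * fs, sd = 0.4), 6, dimnames = list(mice, NULL))
  out <- contrast_of_contrasts(limb, block, lb, bb, frame_rate = fs,
                               n_boot = 500, seed = 4)
  iv <- out$report$intervals
  expect_gte(nrow(iv), 1)
  expect_true(any(iv$start < 7 & iv$end > 1))

  # no-common-mice failure is explicit
  rownames(bb) <- paste0("x", 1:6)
  expect_error(contrast_of_contrasts(limb, block, lb, bb, frame_rate = fs),
               "common")
})
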