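# Trial simulator: determinism, noise structure, response injection, signs.

test_that("zero noise and zero effects give constant tracks", {
  model <- silent_model()
  rec <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous")
  expect_length(rec$tracks, 8)
  n <- timeline_frames(model$timeline)
  for (tr in rec$tracks) {
    expect_length(tr$x, n)
    expect_equal(diff(range(tr$x)), 0)
    expect_equal(diff(range(tr$y)), 0)
    expect_true(all(tr$confidence >= 0 & tr$confidence <= 1))
  }
  # pupil margin points sit one base radius from the center
  expect_equal(
    rec$tracks$pupil_bottom_right$y[1] - rec$tracks$pupil_top_right$y[1],
    model$pupil_diameter_base
  )
})

test_that("sustained window mean recovers offset + amplitude (Monte Carlo)", {
  A <- 2
  model <- silent_model(
    noise_sd = 1, measurement_sd = 0.1,
    sustained_amp = amps(limb_sync = A),
    sustained_onset = 0.5, sustained_duration = 1, sustained_decay = 0.5
  )
  tl <- model$timeline
  fs <- tl$frame_rate
  idx <- embodir:::window_frames(tl$threat_onset + 0.5, tl$threat_onset + 1.5, fs)
  base_x <- embodir:::point_base_xy("pupil_center_right", model)[1]
  means <- vapply(1:1000, function(k) {
    rec <- simulate_trial(model, "m01", k, "artificial_limb", "synchronous",
                          points = "pupil_center_right")
    mean(rec$tracks[[1]]$x[idx]) - base_x
  }, 0)
  expect_lt(abs(mean(means) - A), 4 * sd(means) / sqrt(1000))
})

test_that("simulation is bit-reproducible and point subsets are consistent", {
  model <- cohort_model(n_mice = 2, n_sessions = 1,
                        timeline = tiny_timeline(), seed = 5)
  a <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous")
  b <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous")
  expect_identical(a, b)

  solo <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous",
                         points = "pupil_center_left")
  expect_identical(solo$tracks$pupil_center_left, a$tracks$pupil_center_left)

  other <- simulate_trial(model, "m01", 1, "artificial_limb", "asynchronous")
  expect_false(identical(a$tracks, other$tracks))
})

test_that("flipping the toward-threat sign flips the response exactly", {
  base <- embodir:::point_base_xy("pupil_center_right", silent_model())[1]
  m_pos <- silent_model(fast_amp = amps(limb_sync = 2),
                        sustained_amp = amps(limb_sync = 3))
  m_neg <- silent_model(fast_amp = amps(limb_sync = 2),
                        sustained_amp = amps(limb_sync = 3),
                        eye_sign = c(right = -1, left = -1))
  a <- simulate_trial(m_pos, "m01", 1, "artificial_limb", "synchronous",
                      points = "pupil_center_right")$tracks[[1]]$x
  b <- simulate_trial(m_neg, "m01", 1, "artificial_limb", "synchronous",
                      points = "pupil_center_right")$tracks[[1]]$x
  expect_equal(a - base, -(b - base))
  expect_gt(max(a - base), 0) # positive sign means positive excursion
})

test_that("the baseline segment is stationary", {
  tl <- trial_timeline(pairing_start = 60, threat_onset = 70, threat_hold = 2,
                       frame_rate = 50)
  sd_ou <- 1; tau <- 0.5
  for (seed in 1:3) {
    model <- silent_model(noise_sd = sd_ou, timeline = tl, seed = seed)
    x <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous",
                        points = "pupil_center_right")$tracks[[1]]$x
    half <- 30 * 50
    m1 <- mean(x[1:half]); m2 <- mean(x[(half + 1):(2 * half)])
    # sd of a 30 s OU mean is sd * sqrt(2 tau / T)
    sd_mean <- sd_ou * sqrt(2 * tau / 30)
    expect_lt(abs(m1 - m2), 5 * sqrt(2) * sd_mean)
  }
})

test_that("the threat-only condition has no schedule and only a reflex", {
  model <- silent_model(fast_amp = amps(limb_sync = 4, none = 0.5))
  rec <- simulate_trial(model, "m01", 1, "none", "none",
                        points = "pupil_center_right")
  expect_null(rec$schedule)
  x <- rec$tracks[[1]]$x
  base <- embodir:::point_base_xy("pupil_center_right", model)[1]
  fs <- model$timeline$frame_rate
  pre <- x[1:(model$timeline$threat_onset * fs)]
  expect_equal(diff(range(pre)), 0) # baseline flat without noise
  expect_lt(max(x - base), 0.5 + 1e-9) # only the small no-pairing reflex
  expect_gt(max(x - base), 0.4)

  expect_error(simulate_trial(model, "m01", 1, "none", "synchronous"),
               "none")
})

test_that("per-mouse offsets are stable within mouse and spread across mice", {
  model <- silent_model(n_mice = 30, offset_sd = 5)
  xs <- vapply(sprintf("m%02d", 1:30), function(m) {
    simulate_trial(model, m, 1, "artificial_limb", "synchronous",
                   points = "pupil_center_right")$tracks[[1]]$x[1]
  }, 0)
  again <- simulate_trial(model, "m05", 3, "artificial_limb", "asynchronous",
                          points = "pupil_center_right")$tracks[[1]]$x[1]
  expect_equal(unname(xs["m05"]), again)
  expect_gt(sd(xs), 1) # heterogeneous baselines
})
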