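#' Simulate one trial of the embodiment protocol
#'
#' Generates per-frame tracked coordinates for one trial: per-mouse baseline
#' offset, stationary Ornstein--Uhlenbeck noise plus white measurement noise,
#' and — after the threat onset — a biphasic toward-threat response on the
#' horizontal pupil axis (fast difference-of-exponentials excursion, then a
#' condition-dependent sustained plateau with exponential decay), pupil
#' dilation carried by the vertical separation of the pupil-margin points,
#' and movement bursts on the ear and whisker points. A small fraction of
#' frames emulates tracker failures (large excursion, low confidence).
#'
#' Randomness is organised in substreams: the trial seed is derived from the
#' cohort seed and the trial identity, and each point's noise from the trial
#' seed and the point name. Generating a subset of `points` therefore yields
#' bit-identical series for the points shared with a full run.
#'
#' @param model A [cohort_model()].
#' @param mouse_id Mouse identifier (string).
#' @param session_index Session number, 1-based.
#' @param object_condition `"artificial_limb"`, `"block"` or `"none"`.
#' @param pairing_condition `"synchronous"`, `"asynchronous"` or `"none"`.
#' @param trial_order Position of the trial within its session.
#' @param points Points to generate (default: all points in the model).
#' @param seed Optional override of the derived trial seed.
#' @return An object of class `trial_recording`: condition labels, timeline,
#'   stroke schedule (absent in the threat-only condition) and a named list
#'   of tracks, each with per-frame `x`, `y` (px) and `confidence` in \[0, 1\].
#' @examples
#' model <- cohort_model(n_mice = 1, timeline = trial_timeline(5, 10, 2, 50), seed = 1)
#' rec <- simulate_trial(model, "m01", 1, "artificial_limb", "synchronous")
#' names(rec$tracks)
#' @export
simulate_trial <- function(model, mouse_id, session_index = 1L,
                           object_condition = "artificial_limb",
                           pairing_condition = "synchronous",
                           trial_order = 1L,
                           points = model$points,
                           seed = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  key <- condition_key(object_condition, pairing_condition) # validates labels
  timeline <- model$timeline
  n <- timeline_frames(timeline)
  fs <- timeline$frame_rate
  trial_seed <- seed %||% derive_seed(
    model$seed, mouse_id, session_index, object_condition, pairing_condition
  )

  # Per-mouse horizontal offset, stable across this mouse's trials.
  set.seed(derive_seed(model$seed, "offset", mouse_id))
  mouse_offset <- stats::rnorm(1L) * model$offset_sd

  schedule <- NULL
  if (pairing_condition != "none") {
    schedule <- sample_stroke_schedule(
      pairing_duration = timeline$threat_onset - timeline$pairing_start,
      mode = pairing_condition,
      seed = derive_seed(trial_seed, "schedule")
    )
  }

  tau_post <- (seq_len(n) - 1) / fs - timeline$threat_onset # s, <0 before threat
  response <- model$fast_amp[[key]] * fast_transient(
    tau_post, model$fast_latency, model$fast_rise, model$fast_decay
  ) + model$sustained_amp[[key]] * sustained_plateau(
    tau_post, model$sustained_onset, model$sustained_duration,
    model$sustained_decay
  )
  dilation <- model$dilation_amp * dilation_template(
    tau_post, model$dilation_rise, model$dilation_decay
  )
  burst_scale <- if (max(model$sustained_amp) > 0) {
    model$sustained_amp[[key]] / max(model$sustained_amp)
  } else {
    0
  }
  burst_frames <- which(tau_post >= 0 & tau_post < model$burst_duration)

  tracks <- vector("list", length(points))
  names(tracks) <- points
  for (point in points) {
    side <- point_side(point)
    sgn <- model$eye_sign[[side]]
    base <- point_base_xy(point, model)
    stem <- sub("_(right|left)$", "", point)

    set.seed(derive_seed(trial_seed, "point", point))
    nx <- ou_series(n, model$noise_sd, model$noise_tau, fs)
    ny <- ou_series(n, model$noise_sd, model$noise_tau, fs)
    mx <- stats::rnorm(n) * model$measurement_sd
    my <- stats::rnorm(n) * model$measurement_sd
    confidence <- 0.95 + 0.05 * stats::runif(n)

    x <- base[1] + nx + mx
    y <- base[2] + ny + my

    if (stem %in% c("pupil_center", "pupil_top", "pupil_bottom")) {
      x <- x + mouse_offset + sgn * response
    }
    if (stem == "pupil_top") y <- y - dilation / 2
    if (stem == "pupil_bottom") y <- y + dilation / 2
    if (stem %in% c("ear", "whisker") && length(burst_frames) > 0 &&
        model$burst_sd * burst_scale > 0) {
      jitter_sd <- model$burst_sd * burst_scale
      x[burst_frames] <- x[burst_frames] +
        stats::rnorm(length(burst_frames)) * jitter_sd
      y[burst_frames] <- y[burst_frames] +
        stats::rnorm(length(burst_frames)) * jitter_sd
    }

    if (model$dropout_rate > 0) {
      dropped <- which(stats::runif(n) < model$dropout_rate)
      if (length(dropped) > 0) {
        x[dropped] <- x[dropped] +
          sample(c(-1, 1), length(dropped), replace = TRUE) *
            stats::runif(length(dropped), 20, 60)
        y[dropped] <- y[dropped] +
          sample(c(-1, 1), length(dropped), replace = TRUE) *
            stats::runif(length(dropped), 20, 60)
        confidence[dropped] <- stats::runif(length(dropped), 0, 0.5)
      }
    }

    tracks[[point]] <- list(x = x, y = y, confidence = confidence)
  }

  structure(
    list(
      mouse_id = mouse_id,
      session_index = as.integer(session_index),
      object_condition = object_condition,
      pairing_condition = pairing_condition,
      trial_order = as.integer(trial_order),
      timeline = timeline,
      schedule = schedule,
      eye_sign = model$eye_sign,
      seed = trial_seed,
      tracks = tracks
    ),
    class = "trial_recording"
  )
}

# Stationary OU process sampled at fs Hz: exact discretization
# x[t] = a x[t-1] + e[t], a = exp(-dt/tau), e ~ N(0, sd^2 (1 - a^2)),
# x[0] ~ N(0, sd^2). The recursion runs in C via stats::filter.
ou_series <- function(n, sd, tau, fs) {
  x0 <- stats::rnorm(1L) * sd
  if (n == 0L) return(numeric(0))
  a <- exp(-1 / (tau * fs))
  e <- stats::rnorm(n) * (sd * sqrt(1 - a^2))
  as.numeric(stats::filter(e, a, method = "recursive", init = x0))
}

# Difference-of-exponentials transient, peak-normalized to 1; zero before
# `latency` and for rise == decay degenerates to zero.
fast_transient <- function(tau, latency, rise, decay) {
  out <- numeric(length(tau))
  t <- tau - latency
  on <- t > 0
  if (!any(on) || rise >= decay) return(out)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  out[on] <- (exp(-t[on] / decay) - exp(-t[on] / rise)) / peak
  out
}

# Unit plateau on [onset, onset + duration) after the threat, exponential
# decay beyond; exactly 1 inside the plateau so window means are exact.
sustained_plateau <- function(tau, onset, duration, decay) {
  out <- numeric(length(tau))
  out[tau >= onset & tau < onset + duration] <- 1
  late <- tau >= onset + duration
  out[late] <- exp(-(tau[late] - onset - duration) / decay)
  out
}

# Smooth rise-and-decay dilation template, zero before the threat.
dilation_template <- function(tau, rise, decay) {
  out <- numeric(length(tau))
  on <- tau > 0
  out[on] <- (1 - exp(-tau[on] / rise)) * exp(-tau[on] / decay)
  out
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> mouse %s session %d | %s / %s | %d frames @ %g Hz | %d tracks\n",
    x$mouse_id, x$session_index, x$object_condition, x$pairing_condition,
    length(x$tracks[[1]]$x), x$timeline$frame_rate, length(x$tracks)
  ))
  invisible(x)
}
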