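#' Generative model of a simulated cohort
#'
#' Parameterizes the synthetic cohorts used to exercise the analysis: the
#' trial timeline, per-mouse baseline heterogeneity, autocorrelated
#' (Ornstein--Uhlenbeck) tracking noise, a biphasic threat response (a fast
#' excursion toward the threat followed by a condition-dependent sustained
#' gaze), pupil dilation, ear/whisker movement bursts, and tracker dropouts.
#'
#' Condition-dependent amplitudes are keyed by
#' `limb_sync`, `limb_async`, `block_sync`, `block_async`, `none`
#' (object condition crossed with pairing condition; `none` is the
#' threat-only control). The default ordering
#' `limb_sync > limb_async >= block_sync >= block_async > none`
#' encodes the phenomenology the simulator emulates: the sustained gaze
#' toward the threatened artifact is strongest after synchronous pairing
#' with the limb-shaped artifact, and the threat alone evokes only a small
#' reflex.
#'
#' @param n_mice,n_sessions Cohort size; each session holds one trial per
#'   pairing condition.
#' @param timeline A [trial_timeline()].
#' @param offset_sd Spread of the per-mouse horizontal baseline offset, px.
#' @param noise_sd Stationary sd of the OU baseline noise, px.
#' @param noise_tau Correlation time of the OU noise, s.
#' @param measurement_sd White measurement noise sd, px.
#' @param fast_amp Named amplitudes (px) of the fast threat-onset excursion,
#'   one per condition key.
#' @param fast_latency,fast_rise,fast_decay Timing of the fast transient
#'   (difference of exponentials), s.
#' @param sustained_amp Named amplitudes (px) of the sustained toward-threat
#'   gaze plateau, one per condition key.
#' @param sustained_onset,sustained_duration Plateau window relative to threat
#'   onset, s; after the plateau the component decays with time constant
#'   `sustained_decay` s.
#' @param sustained_decay Post-plateau decay time constant, s.
#' @param pupil_diameter_base Resting vertical pupil diameter, px.
#' @param dilation_amp Pupil dilation amplitude after the threat, px.
#' @param dilation_rise,dilation_decay Dilation kinetics, s.
#' @param burst_sd Extra jitter sd (px) of ear/whisker points during the
#'   post-threat movement burst; scaled per condition by
#'   `sustained_amp / max(sustained_amp)`.
#' @param burst_duration Duration of the movement burst, s.
#' @param dropout_rate Per-frame probability of a tracker failure (large
#'   position excursion, confidence below 0.5).
#' @param eye_sign Named vector with the toward-threat sign of the horizontal
#'   pupil axis for each camera side. The cameras mirror each other, so the
#'   default is `c(right = 1, left = -1)`; the signs are stored in the
#'   manifest so the analysis never guesses them.
#' @param points Tracked points to generate (namespaced by camera side).
#' @param seed Cohort seed; per-mouse, per-trial and per-point seeds are
#'   derived from it with [derive_seed()].
#' @return An object of class `cohort_model`.
#' @examples
#' model <- cohort_model(n_mice = 2, n_sessions = 1, seed = 1)
#' @export
cohort_model <- function(n_mice = 10,
                         n_sessions = 5,
                         timeline = trial_timeline(),
                         offset_sd = 5,
                         noise_sd = 1,
                         noise_tau = 0.5,
                         measurement_sd = 0.1,
                         fast_amp = c(
                           limb_sync = 4, limb_async = 3,
                           block_sync = 3.5, block_async = 3, none = 0.5
                         ),
                         fast_latency = 0.1,
                         fast_rise = 0.05,
                         fast_decay = 0.5,
                         sustained_amp = c(
                           limb_sync = 3, limb_async = 1.5,
                           block_sync = 1.5, block_async = 1, none = 0.25
                         ),
                         sustained_onset = 1,
                         sustained_duration = 6,
                         sustained_decay = 1,
                         pupil_diameter_base = 20,
                         dilation_amp = 2,
                         dilation_rise = 1,
                         dilation_decay = 5,
                         burst_sd = 2,
                         burst_duration = 3,
                         dropout_rate = 0.01,
                         eye_sign = c(right = 1, left = -1),
                         points = default_points(),
                         seed = 1L) {
  timeline <- as_timeline(timeline)
  if (n_mice < 0 || n_sessions < 0) stop("n_mice and n_sessions must be >= 0")
  for (nm in c("offset_sd", "noise_sd", "measurement_sd", "burst_sd")) {
    if (get(nm) < 0) stop(nm, " must be >= 0")
  }
  if (noise_tau <= 0) stop("noise_tau must be > 0")
  keys <- condition_keys()
  for (nm in c("fast_amp", "sustained_amp")) {
    v <- get(nm)
    if (!all(keys %in% names(v))) {
      stop(nm, " must name all condition keys: ", paste(keys, collapse = ", "))
    }
  }
  if (!all(c("right", "left") %in% names(eye_sign)) ||
      !all(abs(eye_sign[c("right", "left")]) == 1)) {
    stop("eye_sign must be c(right = +/-1, left = +/-1)")
  }
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")

  structure(
    list(
      n_mice = as.integer(n_mice), n_sessions = as.integer(n_sessions),
      timeline = timeline,
      offset_sd = offset_sd, noise_sd = noise_sd, noise_tau = noise_tau,
      measurement_sd = measurement_sd,
      fast_amp = fast_amp[keys], fast_latency = fast_latency,
      fast_rise = fast_rise, fast_decay = fast_decay,
      sustained_amp = sustained_amp[keys],
      sustained_onset = sustained_onset,
      sustained_duration = sustained_duration,
      sustained_decay = sustained_decay,
      pupil_diameter_base = pupil_diameter_base,
      dilation_amp = dilation_amp,
      dilation_rise = dilation_rise, dilation_decay = dilation_decay,
      burst_sd = burst_sd, burst_duration = burst_duration,
      dropout_rate = dropout_rate,
      eye_sign = eye_sign[c("right", "left")],
      points = points,
      seed = as.integer(seed)
    ),
    class = "cohort_model"
  )
}

condition_keys <- function() {
  c("limb_sync", "limb_async", "block_sync", "block_async", "none")
}

#' Condition labels
#'
#' Valid object conditions are `artificial_limb`, `block`, `none` (threat
#' only); valid pairing conditions are `synchronous`, `asynchronous`, `none`.
#' `condition_key()` maps a pair of labels to the amplitude key used by
#' [cohort_model()].
#'
#' @param object_condition,pairing_condition Condition labels.
#' @return A single condition key string.
#' @examples
#' condition_key("artificial_limb", "synchronous")
#' @export
condition_key <- function(object_condition, pairing_condition) {
  object_condition <- match.arg(object_condition, c("artificial_limb", "block", "none"))
  pairing_condition <- match.arg(pairing_condition, c("synchronous", "asynchronous", "none"))
  if (object_condition == "none" || pairing_condition == "none") {
    if (object_condition != "none" || pairing_condition != "none") {
      stop("object_condition 'none' requires pairing_condition 'none' and vice versa")
    }
    return("none")
  }
  paste0(
    switch(object_condition, artificial_limb = "limb", block = "block"),
    "_",
    switch(pairing_condition, synchronous = "sync", asynchronous = "async")
  )
}

#' Default tracked points
#'
#' The canonical point set mirrors the face videography: pupil center and the
#' two vertical pupil-margin points on each side (the margin points carry the
#' diameter), plus the left ear and one left whisker. Names are namespaced by
#' camera side.
#'
#' @return Character vector of point names.
#' @export
default_points <- function() {
  c(
    "pupil_center_right", "pupil_top_right", "pupil_bottom_right",
    "pupil_center_left", "pupil_top_left", "pupil_bottom_left",
    "ear_left", "whisker_left"
  )
}

# Camera side of a namespaced point name.
point_side <- function(point) {
  ifelse(grepl("_right$", point), "right",
    ifelse(grepl("_left$", point), "left", NA_character_)
  )
}

# Nominal anatomical coordinates (px, 1440 x 1080 frame) of each point.
point_base_xy <- function(point, model) {
  base <- switch(sub("_(right|left)$", "", point),
    pupil_center = c(900, 540),
    pupil_top = c(900, 540 - model$pupil_diameter_base / 2),
    pupil_bottom = c(900, 540 + model$pupil_diameter_base / 2),
    ear = c(400, 300),
    whisker = c(600, 700),
    stop("unknown point: ", point)
  )
  base
}

#' @export
print.cohort_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_model> %d mice x %d sessions | OU noise sd %g px, tau %g s | ",
      "offsets sd %g px | seed %d\n  sustained amp (px): %s\n"
    ),
    x$n_mice, x$n_sessions, x$noise_sd, x$noise_tau, x$offset_sd, x$seed,
    paste(sprintf("%s=%g", names(x$sustained_amp), x$sustained_amp), collapse = ", ")
  ))
  invisible(x)
}
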