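#' Trial timeline of the embodiment protocol
#'
#' A trial starts with an idle baseline, continues with the visuo-tactile
#' pairing (brush strokes on the hidden real forelimb and on the visible
#' artifact), and ends with a threat probe: a sharp object rapidly moved next
#' to the artifact and held in place. Defaults follow the protocol: 120 s
#' baseline, pairing from 120 s, threat at 240 s held for 10 s, face
#' videography at 200 Hz.
#'
#' @param pairing_start Pairing onset, seconds from trial start.
#' @param threat_onset Threat onset, seconds from trial start.
#' @param threat_hold Duration the threat stays in place, seconds.
#' @param frame_rate Acquisition rate of the tracking cameras, Hz.
#' @return An object of class `trial_timeline`.
#' @examples
#' trial_timeline()
#' trial_timeline(pairing_start = 5, threat_onset = 10, threat_hold = 2, frame_rate = 50)
#' @export
trial_timeline <- function(pairing_start = 120, threat_onset = 240,
                           threat_hold = 10, frame_rate = 200) {
  if (!(0 < pairing_start && pairing_start < threat_onset)) {
    stop("need 0 < pairing_start < threat_onset")
  }
  if (threat_hold <= 0) stop("threat_hold must be > 0")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(
    list(
      baseline_start = 0,
      pairing_start = pairing_start,
      threat_onset = threat_onset,
      threat_hold = threat_hold,
      frame_rate = frame_rate
    ),
    class = "trial_timeline"
  )
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat(sprintf(
    "<trial_timeline> baseline [0, %g) s | pairing [%g, %g) s | threat at %g s held %g s | %g Hz\n",
    x$pairing_start, x$pairing_start, x$threat_onset, x$threat_onset,
    x$threat_hold, x$frame_rate
  ))
  invisible(x)
}

#' Trial duration and frame count
#'
#' A trial covers the baseline, the pairing and the full threat hold:
#' `threat_onset + threat_hold` seconds.
#'
#' @param timeline A [trial_timeline()].
#' @return Duration in seconds, or the total frame count.
#' @export
timeline_duration <- function(timeline) timeline$threat_onset + timeline$threat_hold

#' @rdname timeline_duration
#' @export
timeline_frames <- function(timeline) {
  as.integer(round(timeline_duration(timeline) * timeline$frame_rate))
}

as_timeline <- function(x) {
  if (inherits(x, "trial_timeline")) return(x)
  trial_timeline(
    pairing_start = x$pairing_start, threat_onset = x$threat_onset,
    threat_hold = x$threat_hold, frame_rate = x$frame_rate
  )
}
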