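#' Interpolate low-confidence tracking samples
#'
#' Samples whose tracking likelihood falls below `confidence_threshold` are
#' replaced by linear interpolation between the flanking valid samples;
#' leading and trailing gaps are held at the nearest valid value. Position
#' values that are `NaN` (missing cells) are always treated as invalid.
#'
#' @param values Numeric series (px).
#' @param confidence Per-sample likelihood in \[0, 1\], same length.
#' @param confidence_threshold Samples with confidence strictly below this
#'   are replaced (default 0.9).
#' @return A list with `values` (repaired series), `n_replaced` and
#'   `replaced_fraction`.
#' @examples
#' interpolate_low_confidence(c(2, 100, 4), c(1, 0.1, 1))$values
#' @export
interpolate_low_confidence <- function(values, confidence,
                                       confidence_threshold = 0.9) {
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must be in [0, 1]")
  }
  if (length(values) != length(confidence)) {
    stop("values and confidence must have the same length")
  }
  bad <- confidence < confidence_threshold | !is.finite(values)
  if (all(bad)) {
    stop("unusable track: every sample is below the confidence threshold")
  }
  out <- values
  if (any(bad)) {
    idx <- seq_along(values)
    out[bad] <- if (sum(!bad) == 1) {
      values[!bad] # a single valid sample: hold it everywhere
    } else {
      stats::approx(x = idx[!bad], y = values[!bad], xout = idx[bad],
                    rule = 2)$y
    }
  }
  list(
    values = out,
    n_replaced = sum(bad),
    replaced_fraction = mean(bad)
  )
}

#' Baseline and pre-threat normalization
#'
#' `baseline_normalize()` subtracts the mean of the 120 s pre-pairing
#' baseline (the half-open window `[0, pairing_start)`), correcting for
#' per-trial baseline shifts. `prethreat_normalize()` subtracts the mean of
#' the 1 s immediately preceding the threat, isolating the threat-evoked
#' response from whatever position the eye happened to hold. Both are
#' shift-equivariant and idempotent.
#'
#' @param values Numeric series sampled at `timeline$frame_rate`, starting at
#'   trial time 0.
#' @param timeline A [trial_timeline()].
#' @return Numeric series of the same length, with attribute
#'   `normalization`.
#' @examples
#' tl <- trial_timeline(2, 4, 1, 10)
#' baseline_normalize(rep(3, 50), tl)[1]
#' @export
baseline_normalize <- function(values, timeline) {
  timeline <- as_timeline(timeline)
  idx <- window_frames(0, timeline$pairing_start, timeline$frame_rate)
  if (length(values) < max(idx)) {
    stop("signal does not cover the baseline window [0, ",
         timeline$pairing_start, ") s")
  }
  out <- values - mean(values[idx])
  attr(out, "normalization") <- "baseline_mean"
  out
}

#' @rdname baseline_normalize
#' @export
prethreat_normalize <- function(values, timeline) {
  timeline <- as_timeline(timeline)
  idx <- window_frames(timeline$threat_onset - 1, timeline$threat_onset,
                       timeline$frame_rate)
  if (length(values) < max(idx)) {
    stop("signal does not cover the pre-threat window [",
         timeline$threat_onset - 1, ", ", timeline$threat_onset, ") s")
  }
  out <- values - mean(values[idx])
  attr(out, "normalization") <- "prethreat_1s"
  out
}

#' Vertical pupil diameter
#'
#' Per-frame absolute vertical separation of the two pupil-margin points.
#'
#' @param top_y,bottom_y Numeric y series (px) of the upper and lower pupil
#'   margin; order does not matter.
#' @return Numeric series of diameters (px).
#' @export
pupil_diameter <- function(top_y, bottom_y) {
  if (length(top_y) != length(bottom_y)) {
    stop("top and bottom tracks must have the same length")
  }
  abs(top_y - bottom_y)
}

#' Instantaneous point speed
#'
#' Euclidean norm of the frame-to-frame displacement scaled by the frame
#' rate. The first sample is duplicated so the output keeps the input
#' length.
#'
#' @param x,y Coordinate series (px).
#' @param frame_rate Hz.
#' @return Numeric series of speeds (px/s).
#' @export
point_speed <- function(x, y, frame_rate) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2) stop("point_speed needs at least 2 frames")
  v <- sqrt(diff(x)^2 + diff(y)^2) * frame_rate
  c(v[1], v)
}

#' Average a mouse's trials within a condition
#'
#' Pointwise mean across one mouse's session traces for one condition.
#' Mouse-level averaging always precedes any group averaging: trials are
#' never pooled across mice. Excluded trials are skipped; a mouse with no
#' usable trial is flagged missing rather than silently dropped.
#'
#' @param traces A trials-by-time numeric matrix of one mouse's traces
#'   (aligned time base), or a list of equal-length numeric vectors.
#' @param excluded Logical vector marking trials to skip.
#' @return A list with `mean` (numeric vector, or NULL when no usable
#'   trial), `n_used`, `n_total` and `missing` (TRUE when no usable trial).
#' @examples
#' average_trials_per_mouse(rbind(rep(0, 4), rep(2, 4)))$mean
#' @export
average_trials_per_mouse <- function(traces, excluded = NULL) {
  if (is.list(traces)) {
    lens <- lengths(traces)
    if (length(unique(lens)) > 1) stop("traces must share a common time base")
    traces <- do.call(rbind, traces)
  }
  traces <- as.matrix(traces)
  n_total <- nrow(traces)
  if (n_total < 1) stop("need at least one trial")
  excluded <- excluded %||% rep(FALSE, n_total)
  use <- which(!excluded)
  if (length(use) == 0) {
    return(list(mean = NULL, n_used = 0L, n_total = n_total, missing = TRUE))
  }
  list(
    mean = colMeans(traces[use, , drop = FALSE]),
    n_used = length(use),
    n_total = n_total,
    missing = FALSE
  )
}
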