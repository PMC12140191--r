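#' Detect supra-threshold significance windows
#'
#' Marks the samples of the group difference trace that exceed the bootstrap
#' threshold, merges runs separated by gaps no longer than `merge_gap`,
#' discards runs shorter than `min_duration`, and labels the first two
#' surviving runs (by onset) W1 and W2 — the early threat-onset excursion
#' and the late sustained-gaze window. All intervals are half-open
#' `[start, end)` in seconds relative to threat onset.
#'
#' @param trace A [paired_difference_traces()] result.
#' @param null A [bootstrap_max_null()] result built from the same signal
#'   and sign convention.
#' @param min_duration Minimum surviving run length, s (default 0.1).
#' @param merge_gap Maximum sub-threshold gap merged into a run, s
#'   (default 0.05).
#' @return An object of class `significance_report` with `intervals`
#'   (data.frame `start`, `end`, `duration`), `W1`, `W2` (numeric
#'   `c(start, end)` or NULL), `threshold` and the selection settings. An
#'   empty result (no supra-threshold samples) is valid.
#' @export
detect_windows <- function(trace, null, min_duration = 0.1, merge_gap = 0.05) {
  stopifnot(inherits(trace, "group_difference_trace"),
            inherits(null, "max_null_distribution"))
  time <- trace$time
  dt <- if (length(time) > 1) time[2] - time[1] else 1 / null$frame_rate
  values <- if (null$mode == "absolute") abs(trace$mean) else trace$mean
  supra <- values > null$threshold

  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(starts[runs$values], ends[runs$values])

  if (nrow(iv) > 0 && merge_gap > 0) {
    merged <- iv[1, , drop = FALSE]
    for (r in seq_len(nrow(iv))[-1]) {
      gap <- (iv[r, 1] - merged[nrow(merged), 2] - 1L) * dt
      if (gap <= merge_gap) {
        merged[nrow(merged), 2] <- iv[r, 2]
      } else {
        merged <- rbind(merged, iv[r, ])
      }
    }
    iv <- merged
  }

  if (nrow(iv) > 0) {
    dur <- (iv[, 2] - iv[, 1] + 1L) * dt
    iv <- iv[dur >= min_duration, , drop = FALSE]
  }

  intervals <- data.frame(
    start = time[iv[, 1]],
    end = time[iv[, 2]] + dt,
    duration = (iv[, 2] - iv[, 1] + 1L) * dt
  )

  structure(
    list(
      intervals = intervals,
      W1 = if (nrow(intervals) >= 1) c(intervals$start[1], intervals$end[1]) else NULL,
      W2 = if (nrow(intervals) >= 2) c(intervals$start[2], intervals$end[2]) else NULL,
      threshold = null$threshold,
      mode = null$mode,
      min_duration = min_duration,
      merge_gap = merge_gap
    ),
    class = "significance_report"
  )
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf(
    "<significance_report> threshold %.4g px (%s) | %d supra-threshold window(s)\n",
    x$threshold, x$mode, nrow(x$intervals)
  ))
  if (nrow(x$intervals) > 0) {
    labs <- c("W1", "W2", paste0("run", seq_len(max(0, nrow(x$intervals) - 2)) + 2))
    for (r in seq_len(nrow(x$intervals))) {
      cat(sprintf("  %s: [%.3f, %.3f) s (%.3f s)\n", labs[r],
                  x$intervals$start[r], x$intervals$end[r],
                  x$intervals$duration[r]))
    }
  }
  invisible(x)
}
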