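#' Difference-of-differences contrast between two experiments
#'
#' Compares the strength of the synchronous-minus-asynchronous effect
#' between two experiments (artificial limb vs. block): per common mouse the
#' second-order series (limb sync−async) − (block sync−async) is formed, and
#' the significance threshold comes from applying the same
#' maximum-statistic bootstrap to the per-mouse second-order baseline
#' differences.
#'
#' @param limb,block [paired_difference_traces()] results for the two
#'   experiments (same signal, same time base).
#' @param limb_baseline,block_baseline Mice-by-frames matrices (rownames =
#'   mouse ids) of the per-mouse baseline difference series of each
#'   experiment.
#' @param frame_rate Hz of the baseline series.
#' @param n_boot,quantile_level,segment_length,seed,mode Bootstrap settings,
#'   as in [bootstrap_max_null()].
#' @param min_duration,merge_gap Window-selection settings, as in
#'   [detect_windows()].
#' @return A list with `trace` (a second-order `group_difference_trace`),
#'   `null` (a `max_null_distribution`) and `report`
#'   (a `significance_report`).
#' @export
contrast_of_contrasts <- function(limb, block,
                                  limb_baseline, block_baseline,
                                  frame_rate,
                                  segment_length = 11,
                                  n_boot = 10000, quantile_level = 0.95,
                                  seed = NULL, mode = "signed",
                                  min_duration = 0.1, merge_gap = 0.05) {
  stopifnot(inherits(limb, "group_difference_trace"),
            inherits(block, "group_difference_trace"))
  trace <- paired_difference_traces(limb$per_mouse, block$per_mouse,
                                    time = limb$time)

  common <- intersect(rownames(limb_baseline), rownames(block_baseline))
  if (length(common) == 0) stop("no common mice in the baseline series")
  if (!setequal(common, trace$mice)) {
    stop("baseline series and traces cover different mice")
  }
  second_order <- limb_baseline[common, , drop = FALSE] -
    block_baseline[common, , drop = FALSE]

  null <- bootstrap_max_null(
    second_order, frame_rate = frame_rate, segment_length = segment_length,
    n_boot = n_boot, quantile_level = quantile_level, seed = seed, mode = mode
  )
  report <- detect_windows(trace, null,
                           min_duration = min_duration, merge_gap = merge_gap)
  list(trace = trace, null = null, report = report)
}
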