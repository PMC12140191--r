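#' Baseline-segment maximum-statistic bootstrap
#'
#' Builds the null distribution that controls the family-wise error of the
#' condition-difference trace over the analysis window. Each iteration draws
#' one uniformly random, frame-aligned segment start per mouse from that
#' mouse's baseline difference series, averages the segments pointwise
#' across mice, and records the maximum of the averaged series. The
#' significance threshold is the empirical `quantile_level` quantile of the
#' resulting maxima (order statistic at `ceiling(quantile_level * n_boot)`,
#' inverse-CDF convention).
#'
#' The maximum is taken of the signed averaged series by default (one-sided,
#' toward-threat positive); `mode = "absolute"` takes the maximum of the
#' absolute series instead.
#'
#' @param baseline Mice-by-frames numeric matrix of per-mouse baseline
#'   difference series (a single mouse may be passed as a vector). Must be
#'   free of missing values: interpolate upstream.
#' @param frame_rate Hz.
#' @param segment_length Segment length in seconds (default 11, matching the
#'   analysis window from 1 s before to 10 s after the threat).
#' @param n_boot Number of bootstrap iterations (default 10,000).
#' @param quantile_level Quantile defining the false-positive threshold
#'   (default 0.95, the 5% level).
#' @param seed Optional integer seed.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param start_stride Optional spacing, in seconds, of the admissible
#'   segment starts (e.g. 1 restricts starts to whole seconds). Default:
#'   every frame.
#' @return An object of class `max_null_distribution` with `samples`,
#'   `threshold`, and the settings.
#' @examples
#' base <- matrix(rnorm(2 * 600), 2) # 2 mice, 60 s at 10 Hz
#' null <- bootstrap_max_null(base, frame_rate = 10, segment_length = 5,
#'                            n_boot = 200, seed = 1)
#' null$threshold
#' @export
bootstrap_max_null <- function(baseline, frame_rate, segment_length = 11,
                               n_boot = 10000, quantile_level = 0.95,
                               seed = NULL,
                               mode = c("signed", "absolute"),
                               start_stride = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(baseline))) baseline <- matrix(baseline, nrow = 1)
  baseline <- as.matrix(baseline)
  if (anyNA(baseline)) {
    stop("baseline series contain missing values; interpolate upstream")
  }
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (quantile_level <= 0 || quantile_level > 1) {
    stop("quantile_level must be in (0, 1]")
  }
  m <- nrow(baseline)
  n <- ncol(baseline)
  L <- as.integer(round(segment_length * frame_rate))
  if (L < 1) stop("segment_length too short for the frame rate")
  if (n < L) {
    stop("baseline (", n, " frames) shorter than the ", L, "-frame segment")
  }
  stride <- if (is.null(start_stride)) 1L else {
    as.integer(round(start_stride * frame_rate))
  }
  if (stride < 1) stop("start_stride too small for the frame rate")
  starts_pool <- seq.int(0L, n - L, by = stride) # 0-based start frames

  if (!is.null(seed)) set.seed(seed)
  # one uniformly random start per (iteration, mouse); 0-based frames
  starts <- matrix(0L, n_boot, m)
  for (i in seq_len(m)) {
    starts[, i] <- starts_pool[
      sample.int(length(starts_pool), n_boot, replace = TRUE)
    ]
  }
  samples <- .boot_max_stat(t(baseline), starts, L, mode == "absolute")

  structure(
    list(
      samples = samples,
      threshold = sort(samples)[ceiling(quantile_level * n_boot)],
      segment_length = segment_length,
      n_boot = as.integer(n_boot),
      quantile_level = quantile_level,
      mode = mode,
      frame_rate = frame_rate,
      n_mice = m,
      n_starts = length(starts_pool),
      seed = seed
    ),
    class = "max_null_distribution"
  )
}

#' @export
print.max_null_distribution <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<max_null_distribution> %d samples (%s max of %g s segments, %d mice, ",
      "%d admissible starts)\n  threshold @ q%.3g = %.4g px\n"
    ),
    x$n_boot, x$mode, x$segment_length, x$n_mice, x$n_starts,
    x$quantile_level, x$threshold
  ))
  invisible(x)
}
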