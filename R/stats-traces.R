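#' Per-mouse condition-difference traces
#'
#' Builds the group difference trace for a paired contrast: per mouse the
#' pointwise A − B series (toward-threat sign), then the across-mice mean
#' and SEM. Mice missing either condition are excluded and recorded in
#' `dropped_mice`.
#'
#' @param a,b Mice-by-time numeric matrices with mouse ids as rownames, on a
#'   common time base. Typically the per-mouse condition averages over the
#'   analysis window (1 s before the threat to 10 s after), unnormalized —
#'   the significance analysis runs on raw differences.
#' @param time Time base in seconds relative to threat onset (defaults to
#'   column count spread over `[-1, 10)`, matching the 11 s analysis
#'   window).
#' @return An object of class `group_difference_trace` with `per_mouse`
#'   (matrix), `mean`, `sem`, `n_mice`, `mice`, `dropped_mice`, `time`.
#' @examples
#' a <- rbind(m1 = rep(2, 5), m2 = rep(4, 5))
#' b <- rbind(m1 = rep(0, 5), m2 = rep(0, 5))
#' paired_difference_traces(a, b)$mean[1]
#' @export
paired_difference_traces <- function(a, b, time = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(rownames(a)) || is.null(rownames(b))) {
    stop("a and b need mouse ids as rownames")
  }
  if (ncol(a) != ncol(b)) stop("a and b must share a time base")
  common <- intersect(rownames(a), rownames(b))
  dropped <- setdiff(union(rownames(a), rownames(b)), common)
  if (length(common) == 0) stop("no mice present in both conditions")
  d <- a[common, , drop = FALSE] - b[common, , drop = FALSE]
  n <- length(common)
  m <- colMeans(d)
  sem <- if (n > 1) apply(d, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(d))
  if (is.null(time)) time <- -1 + (seq_len(ncol(d)) - 1) * 11 / ncol(d)
  structure(
    list(
      per_mouse = d, mean = m, sem = sem,
      n_mice = n, mice = common, dropped_mice = dropped,
      time = time
    ),
    class = "group_difference_trace"
  )
}

#' @export
print.group_difference_trace <- function(x, ...) {
  cat(sprintf(
    "<group_difference_trace> %d mice | %d samples on [%.3g, %.3g] s | peak mean %.3g px\n",
    x$n_mice, length(x$mean), min(x$time), max(x$time), max(x$mean)
  ))
  if (length(x$dropped_mice) > 0) {
    cat("  dropped (missing one condition):",
        paste(x$dropped_mice, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-mouse window means
#'
#' Time-mean of each mouse's trace over a quantification window, for both
#' conditions of a contrast. Used to feed the paired signed-rank test on the
#' detected W1/W2 windows; by convention the traces are pre-threat
#' normalized before this quantification.
#'
#' @param a,b Mice-by-time matrices (rownames = mouse ids) on a common time
#'   base.
#' @param time Time base (s relative to threat onset).
#' @param window Numeric `c(start, end)`, half-open, within the time base.
#' @return A data.frame with columns `mouse`, `a`, `b`, `difference`.
#' @export
window_means <- function(a, b, time, window) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != length(time) || ncol(b) != length(time)) {
    stop("time base does not match the traces")
  }
  if (window[1] < min(time) || window[2] > max(time) + diff(time[1:2])) {
    stop("window [", window[1], ", ", window[2], ") lies outside the trace")
  }
  idx <- which(time >= window[1] & time < window[2])
  if (length(idx) == 0) stop("window contains no samples")
  common <- intersect(rownames(a), rownames(b))
  am <- rowMeans(a[common, idx, drop = FALSE])
  bm <- rowMeans(b[common, idx, drop = FALSE])
  data.frame(
    mouse = common, a = unname(am), b = unname(bm),
    difference = unname(am - bm), stringsAsFactors = FALSE
  )
}
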