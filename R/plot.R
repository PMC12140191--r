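#' Plot a condition-difference trace with its significance threshold
#'
#' Draws the across-mice mean difference with an SEM band, the bootstrap
#' threshold as a dashed line, and shades the detected significance windows
#' (W1/W2 style).
#'
#' @param trace A [paired_difference_traces()] result.
#' @param null Optional [bootstrap_max_null()] result (dashed threshold).
#' @param report Optional [detect_windows()] result (shaded windows).
#' @param xlab,ylab,main Usual graphics labels.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `trace`.
#' @export
plot_difference_trace <- function(trace, null = NULL, report = NULL,
                                  xlab = "time from threat onset (s)",
                                  ylab = "condition difference (px)",
                                  main = NULL, ...) {
  stopifnot(inherits(trace, "group_difference_trace"))
  t <- trace$time
  m <- trace$mean
  s <- trace$sem
  ylim <- range(c(m - s, m + s, 0, if (!is.null(null)) null$threshold),
                na.rm = TRUE)
  graphics::plot(t, m, type = "n", xlab = xlab, ylab = ylab,
                 main = main, ylim = ylim, ...)
  if (!is.null(report) && nrow(report$intervals) > 0) {
    for (r in seq_len(nrow(report$intervals))) {
      graphics::rect(report$intervals$start[r], ylim[1],
                     report$intervals$end[r], ylim[2],
                     col = grDevices::grey(0.92), border = NA)
    }
  }
  if (!all(is.na(s))) {
    graphics::polygon(c(t, rev(t)), c(m - s, rev(m + s)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(t, m, col = "steelblue4", lwd = 1.5)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(null)) {
    graphics::abline(h = null$threshold, lty = 2)
  }
  graphics::box()
  invisible(trace)
}
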