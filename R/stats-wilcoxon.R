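#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Two-sided paired signed-rank test as used for the per-mouse window means.
#' Zero differences are dropped before ranking and ties receive midranks.
#' For n (non-zero pairs) up to 25 the p-value is exact, computed from the
#' full distribution of the positive-rank sum over all 2^n sign assignments
#' (evaluated by convolution over the ranks, which enumerates the same
#' distribution without materialising 2^n terms); above 25 a normal
#' approximation with tie-corrected variance is used. Two-sided tail: the
#' probability of a rank sum at least as far from its mean as observed.
#'
#' @param x Per-subject values under condition A, or precomputed paired
#'   differences when `y` is NULL.
#' @param y Optional per-subject values under condition B.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A list of class `signed_rank_test`: `statistic` (positive-rank
#'   sum V), `p.value`, `n` (non-zero pairs), `n_zero`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 1.4, 0.6), rep(0, 5))$p.value # 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must be paired")
    x - y
  }
  if (length(d) < 1) stop("need at least one pair")
  if (anyNA(d)) stop("missing values in paired differences")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; test is degenerate")
    return(structure(
      list(statistic = 0, p.value = 1, n = 0L, n_zero = n_zero,
           method = "degenerate"),
      class = "signed_rank_test"
    ))
  }
  r <- rank(abs(d)) # midranks for ties
  v <- sum(r[d > 0])
  total <- sum(r)
  mu <- total / 2

  if (n <= exact_max) {
    # doubled ranks are integers even with .5 midranks
    r2 <- as.integer(round(2 * r))
    dist <- signed_rank_distribution(r2)
    v2 <- round(2 * v)
    dev <- abs(dist$support - round(2 * mu))
    p <- sum(dist$prob[dev >= abs(v2 - round(2 * mu)) - 1e-9])
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }

  structure(
    list(statistic = v, p.value = p, n = n, n_zero = n_zero, method = method),
    class = "signed_rank_test"
  )
}

# Exact distribution of the positive-rank sum over all 2^n equiprobable sign
# assignments, via the generating-function convolution
# prod_i (1 + z^{r_i}) / 2 on integer (doubled) ranks.
signed_rank_distribution <- function(r2) {
  total <- sum(r2)
  prob <- numeric(total + 1) # index s+1 <-> sum s
  prob[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), prob[seq_len(total + 1 - r)])
    prob <- (prob + shifted) / 2
  }
  list(support = 0:total, prob = prob)
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): V = %g, n = %d%s, two-sided p = %.4g\n",
    x$method, x$statistic, x$n,
    if (x$n_zero > 0) sprintf(" (+%d zero pairs dropped)", x$n_zero) else "",
    x$p.value
  ))
  invisible(x)
}
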