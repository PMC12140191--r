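#' Stroke schedules for the pairing phase
#'
#' During pairing, paint brushes mounted on servos sweep the visible artifact
#' (visual train) and the hidden real forelimb (tactile train). Inter-onset
#' intervals are drawn from an exponential law truncated to
#' `[min_interval, max_interval]` — "Poisson-like" memoryless timing within
#' hard bounds; the untruncated rate defaults to 1/s. In the synchronous
#' condition both brushes fire at the same instants; in the asynchronous
#' condition the two trains are drawn independently from the same law.
#'
#' @param pairing_duration Length of the pairing window, s. Onsets are
#'   expressed relative to the start of the pairing window.
#' @param min_interval,max_interval Truncation bounds of the inter-onset
#'   interval law, s (default 0.6 and 2.0).
#' @param mode `"synchronous"` (tactile train duplicates the visual train) or
#'   `"asynchronous"` (independent trains).
#' @param seed Optional integer seed.
#' @param stroke_duration Duration of one back-and-forth sweep, s (0.3).
#' @param sweep_distance Sweep travel on the limb, mm (6).
#' @param rate Rate of the untruncated exponential, 1/s.
#' @return An object of class `stroke_schedule` with fields `visual_onsets`,
#'   `tactile_onsets` (s, relative to pairing start), `stroke_duration`,
#'   `sweep_distance`, `mode` and the interval-law description.
#' @examples
#' sch <- sample_stroke_schedule(120, mode = "synchronous", seed = 1)
#' range(diff(sch$visual_onsets))
#' @export
sample_stroke_schedule <- function(pairing_duration,
                                   min_interval = 0.6, max_interval = 2.0,
                                   mode = c("synchronous", "asynchronous"),
                                   seed = NULL,
                                   stroke_duration = 0.3, sweep_distance = 6,
                                   rate = 1) {
  mode <- match.arg(mode)
  if (!(0 < min_interval && min_interval <= max_interval)) {
    stop("need 0 < min_interval <= max_interval")
  }
  if (pairing_duration <= max_interval) {
    stop("pairing_duration must exceed max_interval")
  }
  if (rate <= 0) stop("rate must be > 0")
  if (!is.null(seed)) set.seed(seed)

  draw_train <- function() {
    onsets <- numeric(0)
    t <- 0
    repeat {
      t <- t + rtrunc_exp(1L, rate, min_interval, max_interval)
      if (t + stroke_duration > pairing_duration) break
      onsets <- c(onsets, t)
    }
    onsets
  }

  visual <- draw_train()
  tactile <- if (mode == "synchronous") visual else draw_train()

  structure(
    list(
      visual_onsets = visual,
      tactile_onsets = tactile,
      stroke_duration = stroke_duration,
      sweep_distance = sweep_distance,
      mode = mode,
      interval_law = sprintf(
        "truncated_exponential(rate=%g, min=%g, max=%g)",
        rate, min_interval, max_interval
      )
    ),
    class = "stroke_schedule"
  )
}

# Inverse-CDF draws from an exponential(rate) truncated to [a, b].
# Degenerate a == b returns a exactly.
rtrunc_exp <- function(n, rate, a, b) {
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fa <- -expm1(-rate * a) # F(a) of the untruncated law, stable near 0
  fb <- -expm1(-rate * b)
  -log(1 - (fa + u * (fb - fa))) / rate
}

# Mean of the truncated exponential, by numerical integration. Exposed for
# tests and for documenting the expected stroke count in the manifest.
trunc_exp_mean <- function(rate = 1, a = 0.6, b = 2.0) {
  if (a == b) return(a)
  z <- stats::integrate(
    function(x) x * rate * exp(-rate * x), lower = a, upper = b
  )$value
  z / (exp(-rate * a) - exp(-rate * b))
}

#' @export
print.stroke_schedule <- function(x, ...) {
  cat(sprintf(
    "<stroke_schedule> %s | %d visual / %d tactile strokes | %.0f ms sweep over %g mm | %s\n",
    x$mode, length(x$visual_onsets), length(x$tactile_onsets),
    1000 * x$stroke_duration, x$sweep_distance, x$interval_law
  ))
  invisible(x)
}
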