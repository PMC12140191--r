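# Shared fixtures: a short trial timeline so simulated trials stay small,
# and cohort models with selectively silenced components.

tiny_timeline <- function(fs = 50) {
  trial_timeline(pairing_start = 5, threat_onset = 10, threat_hold = 2,
                 frame_rate = fs)
}

zero_amps <- c(limb_sync = 0, limb_async = 0, block_sync = 0,
               block_async = 0, none = 0)

amps <- function(...) {
  v <- zero_amps
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

# Deterministic model: no noise, no offsets, no dropouts, no effects unless
# overridden.
silent_model <- function(..., timeline = tiny_timeline(), seed = 1) {
  defaults <- list(
    n_mice = 1, n_sessions = 1, timeline = timeline,
    offset_sd = 0, noise_sd = 0, measurement_sd = 0,
    fast_amp = zero_amps, sustained_amp = zero_amps,
    dilation_amp = 0, burst_sd = 0, dropout_rate = 0, seed = seed
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(cohort_model, defaults)
}

random_tracking_table <- function(n_frames, n_parts, seed) {
  set.seed(seed)
  parts <- paste0("pt", seq_len(n_parts))
  x <- matrix(rnorm(n_frames * n_parts) * 100, n_frames, n_parts)
  y <- matrix(rnorm(n_frames * n_parts) * 100, n_frames, n_parts)
  if (n_frames > 2) x[sample(n_frames, 1), 1] <- NaN # a missing sample
  cf <- matrix(runif(n_frames * n_parts), n_frames, n_parts)
  tracking_table(x, y, cf, parts, scorer = "tester")
}
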