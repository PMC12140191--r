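# Internal helpers shared across modules.

#' Derive a reproducible child seed
#'
#' Folds an arbitrary sequence of integer or character components into a base
#' seed with a 32-bit multiplicative hash, so that a single cohort seed
#' deterministically yields independent per-trial and per-point seeds. The
#' result always lies in `[0, 2^31 - 2]` and is safe for [set.seed()].
#'
#' @param seed Integer base seed.
#' @param ... Components (integers or strings) identifying the child stream,
#'   e.g. a mouse id, session index and point name.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "m01", 2, "pupil_center_right")
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      unlist(lapply(part, utf8ToInt), use.names = FALSE)
    } else {
      as.numeric(part)
    }
    for (k in codes) {
      # 69069: classic Marsaglia multiplier; products stay < 2^53 so the
      # double arithmetic is exact.
      h <- (h * 69069 + k + 1) %% m
    }
  }
  as.integer(h)
}

# FNV-1a over a character scalar; used to fingerprint configurations in
# reports without pulling in a digest dependency. State is kept in a double
# (exact below 2^53); the xor only ever touches the low 21 bits because
# Unicode code points are < 2^21.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (k in utf8ToInt(x)) {
    low <- h %% 2^21
    h <- (h - low) + bitwXor(as.integer(low), as.integer(k))
    # modular multiply by the FNV prime in 16-bit halves to stay exact
    h1 <- h %/% 2^16
    h0 <- h %% 2^16
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

# Frame indices (1-based) of the half-open time window [from, to) seconds at
# a given frame rate; frame i covers time (i-1)/rate.
window_frames <- function(from, to, frame_rate) {
  i0 <- as.integer(round(from * frame_rate)) + 1L
  i1 <- as.integer(round(to * frame_rate))
  if (i1 < i0) stop("empty frame window [", from, ", ", to, ")")
  i0:i1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
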