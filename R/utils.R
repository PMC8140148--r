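# Internal helpers shared across modules.

# Named RNG substreams: every simulator component draws from its own stream
# derived deterministically from the master seed, so any stage can be
# reproduced in isolation. Offsets are fixed per component name.
.streamOffsets <- c(
  events = 101L, amps = 211L, neuropil = 307L, noise = 401L,
  shifts = 503L, synapses = 601L, puncta = 701L, layout = 809L,
  stats = 907L, pipeline = 1009L
)

.substreamSeed <- function(seed, stream) {
  off <- .streamOffsets[[stream]]
  if (is.null(off)) stop("unknown RNG substream: ", stream)
  # keep within 32-bit signed range
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# Evaluate `expr` under a named substream, restoring the caller's RNG state.
withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.substreamSeed(seed, stream))
  expr
}

.assertScalar <- function(x, field, min = -Inf, max = Inf,
                          strictMin = FALSE, strictMax = FALSE,
                          integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", field), call. = FALSE)
  }
  if ((strictMin && x <= min) || (!strictMin && x < min) ||
      (strictMax && x >= max) || (!strictMax && x > max)) {
    stop(sprintf("'%s' = %g is outside its allowed range", field, x),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", field), call. = FALSE)
  }
  invisible(x)
}

.clampIndex <- function(i, n) pmin(pmax(i, 1L), n)

# Tiny FNV-1a hash over a character string; used only for run manifests.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
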