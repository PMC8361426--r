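# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that a single seed
# per call gives bit-reproducible output without clobbering the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-seed for a named sub-stream of a generator.
sub_seed <- function(seed, stream) {
  offsets <- c(cord = 11L, bold = 23L, motion = 37L, raters = 53L,
               cohort = 71L, noise = 97L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else sum(utf8ToInt(stream))
  (as.integer(seed) * 131L + off) %% .Machine$integer.max
}

is_binary_array <- function(x) {
  is.array(x) && all(x %in% c(0, 1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
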