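# Internal helpers -------------------------------------------------------

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derived from a master seed and a label/value,
# kept within the 32-bit integer range.
derive_seed <- function(seed, value) {
  v <- as.integer(round(abs(value) * 100)) %% 10000L
  (as.integer(seed) * 10019L + v * 7L) %% 2147483629L
}
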