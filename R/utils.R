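`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream. NULL seed means: use the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
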