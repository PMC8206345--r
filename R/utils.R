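# Internal helpers.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic entry points funnel through this so a
# single top-level seed reproduces every artifact.
withLocalSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% .Machine$integer.max)
}

stopIfNot <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
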