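stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive a child seed from a master seed and a stream index; kept well
# below .Machine$integer.max so it is always a valid R seed.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)
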