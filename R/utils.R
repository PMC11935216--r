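# Internal seeding helpers. All stochastic entry points take an integer seed
# and evaluate under withr::with_seed so the caller's RNG state is untouched;
# seed = NULL draws from the current RNG stream.

with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministically derive n child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
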