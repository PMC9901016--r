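# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a stream-specific 32-bit seed from a master seed; keeps independent
# simulation components decoupled while remaining reproducible
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 2654435L + as.integer(stream) * 97L) %% 2147483647L
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

variant_key <- function(position, ref, alt) {
  sprintf("%d%s>%s", as.integer(position), ref, alt)
}

DNA_BASES <- c("A", "C", "G", "T")
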