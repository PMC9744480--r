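# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed runs the code as-is on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Draw a fresh seed from the current RNG stream (used when the caller did
# not supply one, so that the seed can still be recorded in outputs).
# Kept strictly below 2^31 so it survives integer round trips.
draw_seed <- function() {
  sample.int(2147483646L, 1L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

# Scale-aware relative discrepancy used by the oracle-equivalence checks:
# relative for values of magnitude >= 1, absolute below. Quadratic forms
# that are exactly zero in exact arithmetic come out as O(eps) roundoff in
# the double-loop oracle, where a bare relative comparison is meaningless.
rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), 1)
}
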