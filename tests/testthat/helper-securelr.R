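# shared test helpers: tiny formats, sessions with just enough randomness,
# and plaintext oracles all tests compare against

fmt8 <- fp_format(frac_bits = 2, int_bits = 1, ring_bits = 8)
fmt16 <- fp_format(frac_bits = 4, int_bits = 3, ring_bits = 16)
fmt64 <- fp_format()  # a = 12, b = 15, lambda = 64

# a session backed by pooled randomness of the requested sizes
mk_session <- function(fmt, elem = 0, bits = 0, masks = 0, mt = list(),
                       variant = "ripple", seed = NULL) {
  rand <- ti_gen(list(matrix_triples = mt, elem_triples = elem,
                      bit_triples = bits, masked_bits = masks), fmt, seed = seed)
  mpc_session(fmt, rand, variant = variant)
}

open_dec <- function(st, fmt) fp_decode(open_shares(st), fmt)

open_uint <- function(st, fmt) ring_to_uint(open_shares(st), fmt)

# plaintext low-k bits of nonnegative integers (LSB first)
int_bits_oracle <- function(x, k) {
  outer(x, 2^(0:(k - 1)), function(a, p) (a %/% p) %% 2)
}

# exact signed floor(x / 2^d) on ring patterns
signed_shift_oracle <- function(v, d, fmt) {
  ring_from_int(floor(ring_to_int(v, fmt) / 2^d), fmt)
}
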