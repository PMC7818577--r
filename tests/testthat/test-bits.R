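test_that("secure gates reproduce their truth tables over random share splits", {
  fmt <- fmt16
  set.seed(701)
  combos <- expand.grid(p = 0:1, s = 0:1)
  for (rep in 1:50) {
    ctx <- mk_session(fmt, bits = 4, seed = rep)
    sp <- share_secret(combos$p, 1)
    ss <- share_secret(combos$s, 1)
    expect_equal(open_shares(and_gate(sp, ss, ctx)), as.numeric(combos$p & combos$s))
    expect_equal(open_shares(xor_gate(sp, ss)), as.numeric(xor(combos$p, combos$s)))
    expect_equal(open_shares(not_gate(sp)), 1 - combos$p)
  }
})

test_that("AND with a public zero sharing yields zero", {
  ctx <- mk_session(fmt16, bits = 8, seed = 702)
  b <- share_secret(c(0, 1, 1, 0, 1, 0, 1, 1), 1)
  zero <- shared_tensor(numeric(8), numeric(8), 1)
  expect_equal(open_shares(and_gate(b, zero, ctx)), rep(0, 8))
})

test_that("Z_2 traffic is accounted as bit-packed ring words", {
  fmt <- fmt64
  ctx <- mk_session(fmt, bits = 1024, seed = 703)
  p <- share_secret(rep(c(0, 1), 512), 1)
  s <- share_secret(rep(c(1, 1), 512), 1)
  before <- ctx$bytes_a2b
  invisible(and_gate(p, s, ctx))
  # opening d and e: 2 payloads x ceil(1024/64) words x 8 bytes per direction
  expect_equal(ctx$bytes_a2b - before, 2 * ceiling(1024 / 64) * 8)
})

test_that("bit decomposition recovers the binary representation exhaustively at lambda = 8", {
  fmt <- fmt8
  set.seed(704)
  for (variant in c("ripple", "lookahead")) {
    x <- rep(0:255, times = 5)
    ctx <- mk_session(fmt, bits = length(x) * securelr:::decomp_and_gates(8, variant),
                      variant = variant, seed = 704)
    sh <- share_secret(ring_from_int(x, fmt), 8)
    bits <- bit_decompose(sh, 8, ctx)
    expect_equal((bits$alice + bits$bob) %% 2, int_bits_oracle(x, 8),
                 ignore_attr = TRUE)
  }
})

test_that("a (x, 0) share split decomposes to the plain bits of x", {
  fmt <- fmt16
  ctx <- mk_session(fmt, bits = 5000, seed = 705)
  x <- c(0, 1, 37, 255, 65535)
  sh <- shared_tensor(ring_from_int(x, fmt), ring_from_int(numeric(5), fmt), 16)
  bits <- bit_decompose(sh, 16, ctx)
  expect_equal((bits$alice + bits$bob) %% 2, int_bits_oracle(x, 16), ignore_attr = TRUE)
})

test_that("partial decomposition agrees with the low positions of the full one", {
  fmt <- fmt16
  set.seed(706)
  x <- ring_from_int(sample(0:65535, 200, replace = TRUE), fmt)
  sh <- share_secret(x, 16)
  k <- fmt$a + fmt$b + 1
  ctx <- mk_session(fmt, bits = 200 * 2 * 16 + 200 * 2 * k, seed = 706)
  full <- bit_decompose(sh, 16, ctx)
  part <- bit_decompose(sh, k, ctx)
  expect_equal((part$alice + part$bob) %% 2,
               ((full$alice + full$bob) %% 2)[, 1:k])
})

test_that("ripple and lookahead circuits open to identical bits at lambda = 64", {
  fmt <- fmt64
  set.seed(707)
  n <- 2000
  x <- share_secret(fp_encode(stats::runif(n, -2^14, 2^14), fmt), 64)
  need <- n * securelr:::decomp_and_gates(64, "lookahead")
  ripple <- bit_decompose(x, 64, mk_session(fmt, bits = need, seed = 1), variant = "ripple")
  look <- bit_decompose(x, 64, mk_session(fmt, bits = need, seed = 2), variant = "lookahead")
  expect_equal((ripple$alice + ripple$bob) %% 2, (look$alice + look$bob) %% 2)
})

test_that("decomposition round counts are linear (ripple) and logarithmic (lookahead)", {
  fmt <- fmt64
  for (k in c(2, 4, 8, 16, 28, 64)) {
    for (variant in c("ripple", "lookahead")) {
      for (batch in c(1, 64)) {
        ctx <- mk_session(fmt, bits = batch * securelr:::decomp_and_gates(k, variant),
                          variant = variant, seed = k + batch)
        x <- share_secret(ring_from_int(seq_len(batch), fmt), 64)
        invisible(bit_decompose(x, k, ctx))
        want <- if (variant == "ripple") k - 1 else 1 + ceiling(log2(k - 1))
        expect_equal(ctx$rounds, as.integer(want),
                     info = sprintf("k=%d %s batch=%d", k, variant, batch))
      }
    }
  }
})

test_that("bit-to-ring conversion preserves the bit for every masked-bit case", {
  fmt <- fmt16
  # all four (b, r) cases: force the mask by regenerating until both seen
  n <- 10000
  ctx <- mk_session(fmt, masks = n, seed = 708)
  set.seed(7777)
  b <- as.numeric(stats::runif(n) < 0.5)
  sb <- share_secret(b, 1)
  ring <- bit_to_ring(sb, ctx)
  got <- ring_to_uint(open_shares(ring), fmt)
  expect_true(all(got %in% c(0, 1)))
  expect_equal(got, b)
  # the masks consumed covered both r = 0 and r = 1
  r <- (ctx$rand$mb$r2A + ctx$rand$mb$r2B) %% 2
  expect_setequal(unique(r * 2 + b), 0:3)
})

test_that("a batch of conversions costs exactly one round", {
  fmt <- fmt64
  ctx <- mk_session(fmt, masks = 1024, seed = 709)
  sb <- share_secret(rep(c(0, 1), 512), 1)
  before <- ctx$rounds
  invisible(bit_to_ring(sb, ctx))
  expect_equal(ctx$rounds - before, 1L)
})
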