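test_that("sharing reconstructs every ring element and hides it in either share", {
  fmt <- fmt8
  set.seed(501)
  x <- ring_from_int(rep(0:255, times = 20), fmt)
  sh <- share_secret(x, 8)
  expect_true(all(ring_eq(open_shares(sh), x, fmt)))
  # share of zero: alice = -bob
  s0 <- share_secret(ring_from_int(0, fmt), 8)
  expect_true(ring_eq(s0$alice, securelr:::rs_neg(s0$bob, 8), fmt))
  # Z_2 semantics: (1,1) opens to 0
  expect_equal(open_shares(shared_tensor(1, 1, 1)), 0)
  expect_equal(ring_to_uint(open_shares(shared_tensor(
    ring_from_int(3, fp_format(1, 1, 8)), ring_from_int(5, fp_format(1, 1, 8)), 3)),
    fp_format(1, 1, 8)), 0)
})

test_that("alice's share of a fixed secret is uniform over the ring", {
  fmt <- fmt64
  set.seed(502)
  sh <- share_secret(rep(fp_encode(1.0, fmt), 100000), 64)
  # bin by the low 4 bits of alice's share
  bits <- securelr:::rs_bits(sh$alice, 4, 64)
  bins <- as.numeric(bits %*% 2^(0:3))
  p <- stats::chisq.test(tabulate(bins + 1, 16))$p.value
  expect_gt(p, 0.01)
})

test_that("local share operations match plaintext arithmetic exhaustively at lambda = 8", {
  fmt <- fmt8
  set.seed(503)
  grid <- expand.grid(x = 0:255, y = 0:255)
  sx <- share_secret(ring_from_int(grid$x, fmt), 8)
  sy <- share_secret(ring_from_int(grid$y, fmt), 8)
  expect_equal(ring_to_uint(open_shares(local_add(sx, sy)), fmt), (grid$x + grid$y) %% 256)
  expect_equal(ring_to_uint(open_shares(local_sub(sx, sy)), fmt), (grid$x - grid$y) %% 256)
  c5 <- ring_from_int(5, fmt)
  expect_equal(ring_to_uint(open_shares(local_scale(sx, c5)), fmt), (5 * grid$x) %% 256)
  addc <- local_add_const(sx, c5)
  expect_equal(ring_to_uint(open_shares(addc), fmt), (grid$x + 5) %% 256)
  # the constant lands on alice's side only; bob's share is untouched
  expect_true(all(ring_eq(addc$bob, sx$bob, fmt)))
  # subtracting a sharing from itself gives zero
  expect_equal(ring_to_uint(open_shares(local_sub(sx, sx)), fmt), rep(0, nrow(grid)))
})

test_that("local operations generate no channel traffic", {
  ctx <- mk_session(fmt8, seed = 1)
  sx <- share_secret(ring_from_int(1:10, fmt8), 8)
  invisible(local_add(sx, sx)); invisible(local_scale(sx, ring_from_int(3, fmt8)))
  invisible(local_add_const(sx, ring_from_int(3, fmt8)))
  invisible(truncate_shares(sx, 2))
  expect_equal(ctx$rounds, 0L)
  expect_equal(ctx$bytes_a2b, 0)
})

test_that("the trusted initializer's triples satisfy their product invariants", {
  fmt <- fmt8
  rand <- ti_gen(list(matrix_triples = list(c(2, 3, 2)), elem_triples = 2000,
                      bit_triples = 5000, masked_bits = 10000), fmt, seed = 504)
  # scalar ring triples
  u <- ring_to_uint(open_shares(shared_tensor(rand$et$uA, rand$et$uB, 8)), fmt)
  v <- ring_to_uint(open_shares(shared_tensor(rand$et$vA, rand$et$vB, 8)), fmt)
  w <- ring_to_uint(open_shares(shared_tensor(rand$et$wA, rand$et$wB, 8)), fmt)
  expect_equal(w, (u * v) %% 256)
  # matrix triple against a plaintext matmul oracle
  tr <- rand$mt[[1]]
  U <- matrix(ring_to_uint(open_shares(tr$u), fmt), 2, 3)
  V <- matrix(ring_to_uint(open_shares(tr$v), fmt), 3, 2)
  W <- matrix(ring_to_uint(open_shares(tr$w), fmt), 2, 2)
  expect_equal(W, (U %*% V) %% 256)
  # Z_2 triples and masked-bit pairs
  bu <- (rand$bt$uA + rand$bt$uB) %% 2
  bv <- (rand$bt$vA + rand$bt$vB) %% 2
  bw <- (rand$bt$wA + rand$bt$wB) %% 2
  expect_equal(bw, bu * bv)
  r2 <- (rand$mb$r2A + rand$mb$r2B) %% 2
  rR <- ring_to_uint(open_shares(shared_tensor(rand$mb$rRA, rand$mb$rRB, 8)), fmt)
  expect_true(all(r2 %in% c(0, 1)))
  expect_equal(rR, r2)
})

test_that("TI streams are reproducible from the seed and deplete loudly", {
  plan <- list(elem_triples = 50, bit_triples = 50, masked_bits = 10)
  r1 <- ti_gen(plan, fmt16, seed = 505)
  r2 <- ti_gen(plan, fmt16, seed = 505)
  expect_identical(ring_hex(r1$et$uA, fmt16), ring_hex(r2$et$uA, fmt16))
  expect_identical(ring_hex(r1$mb$rRB, fmt16), ring_hex(r2$mb$rRB, fmt16))
  expect_identical(r1$bt$wA, r2$bt$wA)
  ctx <- mpc_session(fmt16, r1)
  x <- share_secret(ring_from_int(1:40, fmt16), 16)
  invisible(securelr:::secure_mul_elem(x, x, ctx))
  expect_error(securelr:::secure_mul_elem(x, x, ctx), "depleted")
  expect_error(securelr:::take_matrix_triple(ctx, c(2, 2, 2)), "depleted|no matrix")
})

test_that("share files round-trip through the binary format", {
  fmt <- fmt64
  set.seed(506)
  m <- fp_encode(matrix(stats::runif(12, -3, 3), 3, 4), fmt)
  sh <- share_secret(m, 64)
  pa <- tempfile(); pb <- tempfile()
  write_share_file(sh$alice, pa, fmt)
  write_share_file(sh$bob, pb, fmt)
  ra <- read_share_file(pa); rb <- read_share_file(pb)
  expect_equal(ra$fmt$a, fmt$a)
  back <- shared_tensor(ra$share, rb$share, fmt$lam)
  expect_equal(fp_decode(open_shares(back), fmt), fp_decode(m, fmt))
  # small rings use lambda-bit words on disk
  f16 <- fmt16
  v <- fp_encode(c(-1.5, 2.25), f16)
  p16 <- tempfile()
  write_share_file(v, p16, f16)
  expect_equal(file.size(p16), 6 + 4 + 8 + 2 * 2)
  expect_equal(as.numeric(read_share_file(p16)$share), v)
  unlink(c(pa, pb, p16))
})

test_that("TI stream files reload into working randomness", {
  plan <- list(matrix_triples = list(c(2, 2, 1)), elem_triples = 20,
               bit_triples = 40, masked_bits = 10)
  rand <- ti_gen(plan, fmt16, seed = 507)
  fa <- tempfile(); fb <- tempfile()
  write_ti_streams(rand, fa, fb, fmt16)
  back <- read_ti_streams(fa, fb, fmt16)
  expect_identical(ring_hex(back$et$uA, fmt16), ring_hex(rand$et$uA, fmt16))
  expect_identical(back$bt$vB, rand$bt$vB)
  expect_identical(ring_hex(as.numeric(back$mt[[1]]$u$alice), fmt16),
                   ring_hex(as.numeric(rand$mt[[1]]$u$alice), fmt16))
  # reloaded triples still multiply correctly
  ctx <- mpc_session(fmt16, back)
  x <- share_secret(fp_encode(1.5, fmt16), 16)
  y <- share_secret(fp_encode(-2, fmt16), 16)
  z <- truncate_shares(secure_mul(x, y, ctx), fmt16$a)
  expect_equal(open_dec(z, fmt16), -3, tolerance = 2^-3)
  unlink(c(fa, fb))
})
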