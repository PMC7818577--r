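#' Clipped-ReLU activation in the clear
#'
#' The MPC-friendly surrogate for the sigmoid: \eqn{\rho(z) = 0} for
#' \eqn{z < -1/2}, \eqn{z + 1/2} for \eqn{-1/2 \le z < 1/2}, and 1 for
#' \eqn{z \ge 1/2} — i.e. `pmin(1, pmax(0, z + 0.5))`.
#'
#' @param z Numeric vector.
#' @return Numeric vector in \eqn{[0, 1]}.
#' @examples
#' rho_clear(c(-5, -0.5, 0, 0.5, 5))
#' @export
rho_clear <- function(z) pmin(1, pmax(0, z + 0.5))

#' Comparison-free secure clipped-ReLU
#'
#' Evaluates \eqn{\rho} directly on additive shares without any secure
#' comparison protocol. Writing \eqn{z' = z + 1/2} (a local constant
#' addition of \eqn{2^{a-1}}), the protocol derives the two facts it needs
#' from a *partial* bit decomposition of \eqn{z'} over the low
#' \eqn{k = a + b + 1} positions:
#' \itemize{
#'   \item `pos` — whether \eqn{z' \ge 0} — is the negation of bit
#'     \eqn{a + b + 1}, because every bit above the fixed-point window
#'     replicates the sign;
#'   \item `geq1` — whether \eqn{z' \ge 1} — is the OR of the \eqn{b} integer
#'     bits (positions \eqn{a+1} to \eqn{a+b}), computed by De Morgan as a
#'     balanced AND tree over the negated bits in \eqn{\lceil \log_2 b \rceil}
#'     rounds.
#' }
#' Both flags are converted to ring sharings \eqn{P, G} in one shared round,
#' and the output is assembled with exactly two sequential secure
#' multiplications, \eqn{o = P \odot (z' + G \odot (2^a - z'))}. \eqn{P} and
#' \eqn{G} are unscaled 0/1 integers, so no truncation is involved and the
#' three-case result is exact: \eqn{2^a} when \eqn{z \ge 1/2}, the encoding of
#' \eqn{z + 1/2} when \eqn{-1/2 \le z < 1/2}, and 0 when \eqn{z < -1/2}.
#' `geq1` is computed unconditionally even when it is masked by \eqn{P = 0};
#' there is no data-dependent control flow.
#'
#' Precondition: \eqn{|z + 1/2| < 2^b}, so the partial-decomposition shortcut
#' applies. The round count is independent of the batch size.
#'
#' @param z A `shared_tensor` (vector of fixed-point values on scale
#'   \eqn{2^a}).
#' @param ctx An [mpc_session()].
#' @return A `shared_tensor` reconstructing to \eqn{Q(\rho(z))} exactly.
#' @export
rho_secure <- function(z, ctx) {
  fmt <- ctx$fmt
  lam <- fmt$lam
  a <- fmt$a; b <- fmt$b
  k <- a + b + 1L
  half <- rs_from_signed(2^(a - 1), lam)
  one <- rs_from_signed(2^a, lam)

  zvec <- st_new(as.numeric(z$alice), as.numeric(z$bob), lam)
  zp <- local_add_const(zvec, half)

  old_phase <- ctx$phase
  set_phase(ctx, "activation_decompose")
  bits <- bit_decompose(zp, k, ctx)

  # pos = NOT(sign bit); only Alice flips
  pos <- not_gate(st_new(bits$alice[, k], bits$bob[, k], 1L))

  # geq1 = OR of the b integer bits, via De Morgan over an AND tree
  set_phase(ctx, "activation_or")
  cols <- (a + 1L):(a + b)
  layer_a <- lapply(cols, function(j) (1 - bits$alice[, j]) %% 2)  # negated bits
  layer_b <- lapply(cols, function(j) bits$bob[, j])
  while (length(layer_a) > 1L) {
    npair <- length(layer_a) %/% 2L
    lhs_a <- unlist(layer_a[2 * seq_len(npair) - 1L])
    lhs_b <- unlist(layer_b[2 * seq_len(npair) - 1L])
    rhs_a <- unlist(layer_a[2 * seq_len(npair)])
    rhs_b <- unlist(layer_b[2 * seq_len(npair)])
    prod <- and_gate(st_new(lhs_a, lhs_b, 1L), st_new(rhs_a, rhs_b, 1L), ctx)
    n <- length(layer_a[[1]])
    new_a <- lapply(seq_len(npair), function(i) prod$alice[(i - 1) * n + seq_len(n)])
    new_b <- lapply(seq_len(npair), function(i) prod$bob[(i - 1) * n + seq_len(n)])
    if (length(layer_a) %% 2L == 1L) {
      new_a <- c(new_a, layer_a[length(layer_a)])
      new_b <- c(new_b, layer_b[length(layer_b)])
    }
    layer_a <- new_a; layer_b <- new_b
  }
  geq1 <- not_gate(st_new(layer_a[[1]], layer_b[[1]], 1L))

  set_phase(ctx, "activation_convert")
  conv <- bit_to_ring(pos, ctx, more = list(geq1))
  P <- conv[[1]]; G <- conv[[2]]

  set_phase(ctx, "activation_mul")
  # u = z' + G * (2^a - z'), then o = P * u; no truncation anywhere
  tmono <- st_new(rs_sub(one, zp$alice, lam), rs_neg(zp$bob, lam), lam)
  u <- local_add(zp, secure_mul_elem(G, tmono, ctx))
  o <- secure_mul_elem(P, u, ctx)
  set_phase(ctx, old_phase)
  o
}
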