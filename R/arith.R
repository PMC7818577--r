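#' Beaver-triple secure multiplication
#'
#' Multiplies two secret-shared operands using one pre-distributed Beaver
#' triple \eqn{(U, V, W)} with \eqn{W = U V}: the parties open
#' \eqn{D = X - U} and \eqn{E = Y - V} in a single simultaneous exchange (one
#' round, whatever the dimensions), then locally assemble
#' \eqn{Z = W + D V + U E + D E}, the asymmetric \eqn{D E} term contributed by
#' Alice alone. The same protocol covers scalar products, inner products and
#' matrix products; only the triple's shape differs.
#'
#' The product of two fixed-point encodings lives on scale \eqn{2^{2a}}; the
#' caller truncates with [truncate_shares()] when (and only when) rescaling is
#' required — deferring a single truncation to the end of a whole inner
#' product is exactly what makes the accounting cheap.
#'
#' @param x,y `shared_tensor`s over the ring: conformable matrices for a
#'   matrix product, or equal-length vectors for an elementwise product.
#' @param ctx An [mpc_session()] with randomness attached.
#' @return A `shared_tensor` reconstructing to \eqn{X Y \bmod 2^\lambda}.
#' @export
secure_mul <- function(x, y, ctx) {
  if (!is.null(dim(x$alice)) && !is.null(dim(y$alice)))
    secure_matmul(x, y, ctx)
  else
    secure_mul_elem(x, y, ctx)
}

secure_matmul <- function(x, y, ctx) {
  lam <- ctx$fmt$lam
  dx <- dim(x$alice); dy <- dim(y$alice)
  if (dx[2] != dy[1]) stop("shared matrix dimensions are not conformable")
  tr <- take_matrix_triple(ctx, c(dx[1], dx[2], dy[2]))
  d_sh <- local_sub(x, tr$u)
  e_sh <- local_sub(y, tr$v)
  opened <- ch_exchange(ctx, list(d_sh, e_sh))
  D <- opened[[1]]; E <- opened[[2]]
  za <- rs_add(rs_add(as.numeric(tr$w$alice),
                      as.numeric(rs_matmul(D, tr$v$alice, lam)), lam),
               rs_add(as.numeric(rs_matmul(tr$u$alice, E, lam)),
                      as.numeric(rs_matmul(D, E, lam)), lam), lam)
  zb <- rs_add(as.numeric(tr$w$bob),
               rs_add(as.numeric(rs_matmul(D, tr$v$bob, lam)),
                      as.numeric(rs_matmul(tr$u$bob, E, lam)), lam), lam)
  dim(za) <- c(dx[1], dy[2]); dim(zb) <- c(dx[1], dy[2])
  tally_add(ctx, "ring_mults", dx[1] * dx[2] * dy[2])
  tally_add(ctx, "matrix_triples", 1)
  st_new(za, zb, lam)
}

secure_mul_elem <- function(x, y, ctx) {
  lam <- ctx$fmt$lam
  n <- st_len(x)
  if (st_len(y) != n) stop("shared vector lengths differ")
  tr <- take_elem_triples(ctx, n)
  xv <- st_new(as.numeric(x$alice), as.numeric(x$bob), lam)
  yv <- st_new(as.numeric(y$alice), as.numeric(y$bob), lam)
  opened <- ch_exchange(ctx, list(local_sub(xv, tr$u), local_sub(yv, tr$v)))
  D <- opened[[1]]; E <- opened[[2]]
  za <- rs_add(rs_add(tr$w$alice, rs_mul(D, tr$v$alice, lam), lam),
               rs_add(rs_mul(tr$u$alice, E, lam), rs_mul(D, E, lam), lam), lam)
  zb <- rs_add(tr$w$bob,
               rs_add(rs_mul(D, tr$v$bob, lam), rs_mul(tr$u$bob, E, lam), lam), lam)
  tally_add(ctx, "ring_mults", n)
  tally_add(ctx, "elem_triples", n)
  st_new(za, zb, lam)
}

#' Batched secure multiplications sharing one round
#'
#' Issues several independent secure multiplications together: all the masked
#' differences are opened in a single simultaneous exchange, so the whole
#' batch costs exactly one round — the batching contract that the training
#' protocol and the activation rely on.
#'
#' @param pairs A list of `list(x = , y = )` pairs of shared matrices.
#' @param ctx An [mpc_session()].
#' @return A list of `shared_tensor` products, in input order.
#' @export
secure_mul_batch <- function(pairs, ctx) {
  lam <- ctx$fmt$lam
  prep <- lapply(pairs, function(p) {
    dx <- dim(p$x$alice); dy <- dim(p$y$alice)
    if (is.null(dx)) { dx <- c(length(p$x$alice), 1L); dim(p$x$alice) <- dx; dim(p$x$bob) <- dx }
    if (is.null(dy)) { dy <- c(length(p$y$alice), 1L); dim(p$y$alice) <- dy; dim(p$y$bob) <- dy }
    tr <- take_matrix_triple(ctx, c(dx[1], dx[2], dy[2]))
    list(x = p$x, y = p$y, tr = tr, dx = dx, dy = dy)
  })
  payloads <- unlist(lapply(prep, function(p)
    list(local_sub(p$x, p$tr$u), local_sub(p$y, p$tr$v))), recursive = FALSE)
  opened <- ch_exchange(ctx, payloads)
  out <- vector("list", length(prep))
  for (i in seq_along(prep)) {
    p <- prep[[i]]
    D <- opened[[2 * i - 1]]; E <- opened[[2 * i]]
    za <- rs_add(rs_add(as.numeric(p$tr$w$alice),
                        as.numeric(rs_matmul(D, p$tr$v$alice, lam)), lam),
                 rs_add(as.numeric(rs_matmul(p$tr$u$alice, E, lam)),
                        as.numeric(rs_matmul(D, E, lam)), lam), lam)
    zb <- rs_add(as.numeric(p$tr$w$bob),
                 rs_add(as.numeric(rs_matmul(D, p$tr$v$bob, lam)),
                        as.numeric(rs_matmul(p$tr$u$bob, E, lam)), lam), lam)
    dim(za) <- c(p$dx[1], p$dy[2]); dim(zb) <- c(p$dx[1], p$dy[2])
    tally_add(ctx, "ring_mults", p$dx[1] * p$dx[2] * p$dy[2])
    tally_add(ctx, "matrix_triples", 1)
    out[[i]] <- st_new(za, zb, lam)
  }
  out
}

#' Communication-free truncation of shared fixed-point values
#'
#' Rescales a shared product by \eqn{2^{-d}} with zero messages: Alice maps
#' her share to \eqn{\lfloor x_A / 2^d \rfloor} and Bob maps his to
#' \eqn{q - \lfloor (q - x_B)/2^d \rfloor \bmod q}. The reconstruction equals
#' the two's-complement \eqn{\lfloor x / 2^d \rfloor} up to an error in
#' \eqn{\{-1, 0, +1\}} least-significant bits — except with probability
#' \eqn{2^{d+1-\lambda}}, when the result is arbitrary (the protocol is
#' oblivious and cannot signal the failure).
#'
#' @param p A `shared_tensor` over the ring.
#' @param d Number of bits to drop; the fractional width \eqn{a} in every use
#'   inside the training protocol.
#' @param ctx Optional session; used only to record truncation-event share
#'   splits when the strong-oracle replay is active.
#' @return The truncated `shared_tensor`.
#' @export
truncate_shares <- function(p, d, ctx = NULL) {
  st_trunc(p, as.integer(d), record = ctx)
}

#' Truncation failure probability
#'
#' The probability that one share-local truncation by the fractional width
#' \eqn{a} lands outside the \eqn{\pm 1}-LSB error model and yields an
#' arbitrary ring element: \eqn{2^{a + 1 - \lambda}}. At the default
#' operating point (\eqn{a = 12}, \eqn{\lambda = 64}) this is \eqn{2^{-51}},
#' small enough that even billions of truncations are unlikely to corrupt a
#' weight.
#'
#' @param fmt An [fp_format()].
#' @return The failure probability (a bare double).
#' @export
trunc_failure_prob <- function(fmt) 2^(fmt$a + 1 - fmt$lam)
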