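#' Additive secret sharing and local share operations
#'
#' A *shared tensor* holds the two parties' additive shares of a vector or
#' matrix of ring elements: `alice + bob (mod 2^mod_bits)` reconstructs the
#' secret. `mod_bits` is either the ring width \eqn{\lambda} (arithmetic
#' sharing, opaque pattern doubles) or 1 (\eqn{Z_2} sharing, plain 0/1
#' values). Both sides are kept in one object because the whole protocol
#' stack runs as an instrumented in-process simulation of the two data
#' processors.
#'
#' @name shared-tensors
NULL

st_new <- function(alice, bob, mod_bits) {
  structure(list(alice = alice, bob = bob, mod_bits = as.integer(mod_bits)),
            class = "shared_tensor")
}

#' Construct a shared tensor from explicit shares
#'
#' Mostly useful when reloading shares from disk ([read_share_file()]) or
#' writing tests; [share_secret()] is the normal entry point.
#'
#' @param alice,bob The two parties' shares (same shape).
#' @param mod_bits Modulus width (\eqn{\lambda}, or 1 for \eqn{Z_2}).
#' @return A `shared_tensor`.
#' @export
shared_tensor <- function(alice, bob, mod_bits) {
  if (length(alice) != length(bob)) stop("share shapes differ")
  st_new(alice, bob, mod_bits)
}

#' @export
print.shared_tensor <- function(x, ...) {
  d <- if (is.null(dim(x$alice))) length(x$alice) else paste(dim(x$alice), collapse = " x ")
  cat(sprintf("<shared_tensor> %s element(s), Z_{2^%d} sharing\n", d, x$mod_bits))
  invisible(x)
}

st_len <- function(x) length(x$alice)

#' Secret-share ring elements between the two parties
#'
#' Alice's share is drawn uniformly at random from the ring; Bob's share is
#' the modular difference, so that the pair reconstructs the secret while
#' either share alone is uniform.
#'
#' @param x Ring elements (pattern doubles) for `mod_bits > 1`, or a 0/1
#'   vector for a \eqn{Z_2} sharing.
#' @param mod_bits Modulus width: \eqn{\lambda} for arithmetic shares, 1 for
#'   bit shares.
#' @return A `shared_tensor`.
#' @export
share_secret <- function(x, mod_bits) {
  mod_bits <- as.integer(mod_bits)
  if (mod_bits == 1L) {
    v <- as.numeric(x)
    a <- as.numeric(stats::runif(length(v)) < 0.5)
    b <- (v + a) %% 2
    out <- st_new(a, b, 1L)
  } else {
    v <- as.numeric(x)
    a <- rs_rand(length(v), mod_bits)
    b <- rs_sub(v, a, mod_bits)
    out <- st_new(a, b, mod_bits)
  }
  if (!is.null(dim(x))) {
    dim(out$alice) <- dim(x)
    dim(out$bob) <- dim(x)
  }
  out
}

#' Reconstruct the secret from both shares
#'
#' Combines the two shares by modular addition (XOR for \eqn{Z_2} sharings).
#' This is the "open" step: in a deployment each party would send its share
#' to the other. When a session `ctx` is supplied the exchange is accounted
#' for on the channel (one round).
#'
#' @param p A `shared_tensor`.
#' @param ctx Optional `mpc_session`; when given, the open is charged to the
#'   channel counters.
#' @return The reconstructed ring elements (or 0/1 vector).
#' @export
open_shares <- function(p, ctx = NULL) {
  if (!is.null(ctx)) return(ch_exchange(ctx, list(p))[[1]])
  reconstruct(p)
}

reconstruct <- function(p) {
  out <- if (p$mod_bits == 1L) (p$alice + p$bob) %% 2
         else rs_add(as.numeric(p$alice), as.numeric(p$bob), p$mod_bits)
  if (!is.null(dim(p$alice))) dim(out) <- dim(p$alice)
  out
}

check_same_modulus <- function(p, s) {
  if (!identical(p$mod_bits, s$mod_bits))
    stop("protocol error: shares live in different rings (Z_{2^", p$mod_bits,
         "} vs Z_{2^", s$mod_bits, "})")
}

#' Local (communication-free) operations on shares
#'
#' Addition, subtraction and scaling by a public constant act share-wise;
#' adding a public constant adjusts Alice's share only while Bob's share is
#' unchanged. None of these touch the channel, which is assertable from the
#' session's byte counters.
#'
#' @param p,s `shared_tensor`s over the same modulus.
#' @param c A public ring constant (pattern double), e.g. `fp_encode(eta, fmt)`.
#' @return A `shared_tensor`.
#' @name local-ops
NULL

#' @rdname local-ops
#' @export
local_add <- function(p, s) {
  check_same_modulus(p, s)
  if (p$mod_bits == 1L) st_new((p$alice + s$alice) %% 2, (p$bob + s$bob) %% 2, 1L)
  else st_new(keep_dim(rs_add(as.numeric(p$alice), as.numeric(s$alice), p$mod_bits), p$alice, s$alice),
              keep_dim(rs_add(as.numeric(p$bob), as.numeric(s$bob), p$mod_bits), p$bob, s$bob),
              p$mod_bits)
}

#' @rdname local-ops
#' @export
local_sub <- function(p, s) {
  check_same_modulus(p, s)
  if (p$mod_bits == 1L) st_new((p$alice - s$alice) %% 2, (p$bob - s$bob) %% 2, 1L)
  else st_new(keep_dim(rs_sub(as.numeric(p$alice), as.numeric(s$alice), p$mod_bits), p$alice, s$alice),
              keep_dim(rs_sub(as.numeric(p$bob), as.numeric(s$bob), p$mod_bits), p$bob, s$bob),
              p$mod_bits)
}

#' @rdname local-ops
#' @export
local_scale <- function(p, c) {
  st_new(keep_dim(rs_mul(as.numeric(p$alice), as.numeric(c), p$mod_bits), p$alice, p$alice),
         keep_dim(rs_mul(as.numeric(p$bob), as.numeric(c), p$mod_bits), p$bob, p$bob),
         p$mod_bits)
}

#' @rdname local-ops
#' @export
local_add_const <- function(p, c) {
  st_new(keep_dim(rs_add(as.numeric(p$alice), as.numeric(c), p$mod_bits), p$alice, p$alice),
         p$bob, p$mod_bits)
}

# a sharing of a public/constant tensor: Alice holds the value, Bob zeros
st_public <- function(x, mod_bits) {
  zero <- if (mod_bits == 1L) numeric(length(x)) else rs_from_signed(numeric(length(x)), mod_bits)
  if (!is.null(dim(x))) dim(zero) <- dim(x)
  st_new(x, zero, as.integer(mod_bits))
}

# local truncation by d bits (pi_trunc): each party transforms its own share;
# no messages. Reconstruction equals the two's-complement floor(x / 2^d) up
# to +/-1 LSB except with probability 2^(d+1-lambda), when it is arbitrary.
st_trunc <- function(p, d, record = NULL) {
  if (!is.null(record)) record_trunc(record, p)
  st_new(keep_dim(rs_trunc(as.numeric(p$alice), d, p$mod_bits, 0L), p$alice, p$alice),
         keep_dim(rs_trunc(as.numeric(p$bob), d, p$mod_bits, 1L), p$bob, p$bob),
         p$mod_bits)
}
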