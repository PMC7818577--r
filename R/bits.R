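#' Secret-shared bit vectors
#'
#' A `bit_shares` object holds \eqn{Z_2} sharings of `k` bit positions for a
#' batch of instances: each party's side is a `batch x k` 0/1 matrix, column
#' 1 the least-significant bit. Reconstructing columns 1..k yields the low-k
#' bits of the corresponding ring value.
#'
#' @name bit-shares
NULL

bs_new <- function(alice, bob) {
  structure(list(alice = alice, bob = bob, k = ncol(alice), batch = nrow(alice)),
            class = "bit_shares")
}

#' @export
print.bit_shares <- function(x, ...) {
  cat(sprintf("<bit_shares> %d bit position(s) x %d instance(s)\n", x$k, x$batch))
  invisible(x)
}

bs_open <- function(x) (x$alice + x$bob) %% 2

# Z_2 gates --------------------------------------------------------------------

#' Secure gates over \eqn{Z_2} sharings
#'
#' `and_gate()` is a Beaver multiplication in \eqn{Z_2} (one round; all gates
#' passed in one call share that round). `xor_gate()` is local share-wise
#' addition mod 2 and `not_gate()` flips Alice's share only; neither touches
#' the channel.
#'
#' @param p,s `shared_tensor`s over \eqn{Z_2} (equal length 0/1 share vectors).
#' @param ctx An [mpc_session()] (needed by `and_gate` for triples).
#' @return A `shared_tensor` over \eqn{Z_2}.
#' @export
and_gate <- function(p, s, ctx) {
  n <- st_len(p)
  if (st_len(s) != n) stop("Z_2 operand lengths differ")
  tr <- take_bit_triples(ctx, n)
  pv <- st_new(as.numeric(p$alice), as.numeric(p$bob), 1L)
  sv <- st_new(as.numeric(s$alice), as.numeric(s$bob), 1L)
  opened <- ch_exchange(ctx, list(local_sub(pv, tr$u), local_sub(sv, tr$v)))
  d <- opened[[1]]; e <- opened[[2]]
  za <- (tr$w$alice + d * tr$v$alice + tr$u$alice * e + d * e) %% 2
  zb <- (tr$w$bob + d * tr$v$bob + tr$u$bob * e) %% 2
  tally_add(ctx, "and_gates", n)
  st_new(za, zb, 1L)
}

#' @rdname and_gate
#' @export
xor_gate <- function(p, s) {
  st_new((as.numeric(p$alice) + as.numeric(s$alice)) %% 2,
         (as.numeric(p$bob) + as.numeric(s$bob)) %% 2, 1L)
}

#' @rdname and_gate
#' @export
not_gate <- function(p) {
  st_new((1 - as.numeric(p$alice)) %% 2, as.numeric(p$bob), 1L)
}

# bit decomposition ------------------------------------------------------------

#' Secure bit decomposition of arithmetic shares
#'
#' Converts a batch of \eqn{Z_{2^\lambda}} sharings into per-bit \eqn{Z_2}
#' sharings of the low `k` bit positions. Each party enters the bits of its
#' own additive share as trivial \eqn{Z_2} sharings and the parties jointly
#' evaluate a binary-addition circuit with secure AND gates: with Alice's
#' share bits \eqn{y_i} and Bob's \eqn{z_i}, carries follow
#' \eqn{c_1 = 0,\; c_{i+1} = (y_i \wedge z_i) \oplus (c_i \wedge (y_i \oplus z_i))}
#' and the output bit is \eqn{x_i = y_i \oplus z_i \oplus c_i}.
#'
#' Two circuits are provided: the literal ripple-carry reference
#' (\eqn{k - 1} rounds) and a Kogge-Stone carry-lookahead network whose
#' generate/propagate pairs are combined in a prefix scan
#' (\eqn{1 + \lceil \log_2(k-1) \rceil} rounds). Both consume one AND per
#' generate plus the carry-combination ANDs; the batch size never changes the
#' round count because every gate layer is issued as one call.
#'
#' @param x A `shared_tensor` over the ring (vector of instances).
#' @param k Number of low bit positions to produce (`k <= lambda`); a partial
#'   decomposition with `k = a + b + 1` is all the activation needs.
#' @param ctx An [mpc_session()].
#' @param variant `"ripple"` or `"lookahead"`; defaults to the session's.
#' @return A `bit_shares` object (`batch x k`).
#' @export
bit_decompose <- function(x, k, ctx, variant = NULL) {
  variant <- variant %||% ctx$variant
  lam <- ctx$fmt$lam
  k <- as.integer(k)
  if (k > lam) stop("cannot decompose ", k, " bit positions from a ", lam, "-bit ring")
  ya <- rs_bits(as.numeric(x$alice), k, lam)   # batch x k, Alice's plaintext bits
  zb <- rs_bits(as.numeric(x$bob), k, lam)     # batch x k, Bob's plaintext bits
  n <- nrow(ya)
  # y_i shared as (bit, 0), z_i as (0, bit); p_i = y_i xor z_i is local
  pa <- ya; pb <- zb
  xa <- matrix(0, n, k); xb <- matrix(0, n, k)
  xa[, 1] <- pa[, 1]; xb[, 1] <- pb[, 1]
  if (k >= 2L) {
    K <- k - 1L
    # generate layer: g_i = y_i AND z_i for i = 1..K, one batched round
    g <- and_gate(st_new(as.numeric(ya[, 1:K]), numeric(n * K), 1L),
                  st_new(numeric(n * K), as.numeric(zb[, 1:K]), 1L), ctx)
    ga <- matrix(g$alice, n, K); gb <- matrix(g$bob, n, K)
    if (variant == "ripple") {
      ca <- ga[, 1]; cb <- gb[, 1]                       # c_2 = g_1 (c_1 = 0)
      xa[, 2] <- (pa[, 2] + ca) %% 2; xb[, 2] <- (pb[, 2] + cb) %% 2
      i <- 2L
      while (i <= K) {
        cp <- and_gate(st_new(ca, cb, 1L),
                       st_new(pa[, i], pb[, i], 1L), ctx)  # c_i AND p_i
        ca <- (ga[, i] + cp$alice) %% 2
        cb <- (gb[, i] + cp$bob) %% 2
        xa[, i + 1L] <- (pa[, i + 1L] + ca) %% 2
        xb[, i + 1L] <- (pb[, i + 1L] + cb) %% 2
        i <- i + 1L
      }
    } else {
      # Kogge-Stone prefix over (G, P) pairs; combine is
      # (G2,P2) o (G1,P1) = (G2 xor (P2 and G1), P2 and P1)
      Ga <- ga; Gb <- gb
      Pa <- pa[, 1:K, drop = FALSE]; Pb <- pb[, 1:K, drop = FALSE]
      s <- 1L
      while (s < K) {
        idx <- (s + 1L):K
        lhsa <- cbind(Pa[, idx, drop = FALSE], Pa[, idx, drop = FALSE])
        lhsb <- cbind(Pb[, idx, drop = FALSE], Pb[, idx, drop = FALSE])
        rhsa <- cbind(Ga[, idx - s, drop = FALSE], Pa[, idx - s, drop = FALSE])
        rhsb <- cbind(Gb[, idx - s, drop = FALSE], Pb[, idx - s, drop = FALSE])
        prod <- and_gate(st_new(as.numeric(lhsa), as.numeric(lhsb), 1L),
                         st_new(as.numeric(rhsa), as.numeric(rhsb), 1L), ctx)
        nn <- n * length(idx)
        pga <- matrix(prod$alice[seq_len(nn)], n); pgb <- matrix(prod$bob[seq_len(nn)], n)
        ppa <- matrix(prod$alice[nn + seq_len(nn)], n); ppb <- matrix(prod$bob[nn + seq_len(nn)], n)
        Ga[, idx] <- (Ga[, idx, drop = FALSE] + pga) %% 2
        Gb[, idx] <- (Gb[, idx, drop = FALSE] + pgb) %% 2
        Pa[, idx] <- ppa; Pb[, idx] <- ppb
        s <- 2L * s
      }
      # c_{i+1} = prefix G_i
      xa[, 2:k] <- (pa[, 2:k, drop = FALSE] + Ga) %% 2
      xb[, 2:k] <- (pb[, 2:k, drop = FALSE] + Gb) %% 2
    }
  }
  bs_new(xa, xb)
}

#' Convert \eqn{Z_2} bit sharings to ring sharings
#'
#' The masked-bit construction: with a pre-distributed pair sharing the same
#' random bit \eqn{r} both in \eqn{Z_2} and in \eqn{Z_{2^\lambda}}, the
#' parties open \eqn{c = b \oplus r} (one round for the whole batch, and for
#' every batch passed in `more`) and locally output
#' \eqn{[b]_{2^\lambda} = c + (1 - 2c) \cdot [r]_{2^\lambda}}, the constant
#' \eqn{c} added on Alice's side.
#'
#' @param p A `shared_tensor` over \eqn{Z_2} (batch of bits).
#' @param ctx An [mpc_session()].
#' @param more Optional list of further \eqn{Z_2} `shared_tensor`s converted
#'   in the same round.
#' @return A ring `shared_tensor` (or a list of them if `more` is given)
#'   reconstructing to the same bits as integers.
#' @export
bit_to_ring <- function(p, ctx, more = NULL) {
  lam <- ctx$fmt$lam
  batches <- c(list(p), more %||% list())
  masks <- lapply(batches, function(b) take_masked_bits(ctx, st_len(b)))
  masked <- purrr::map2(batches, masks, function(b, mk) xor_gate(b, mk$r_bit))
  opened <- ch_exchange(ctx, masked)
  out <- purrr::pmap(list(batches, masks, opened), function(b, mk, cbits) {
    tally_add(ctx, "masked_bits", st_len(b))
    sign <- rs_from_signed(1 - 2 * cbits, lam)
    za <- rs_add(rs_from_signed(cbits, lam),
                 rs_mul(sign, mk$r_ring$alice, lam), lam)
    zb <- rs_mul(sign, mk$r_ring$bob, lam)
    st_new(za, zb, lam)
  })
  if (is.null(more)) out[[1]] else out
}
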