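#' Trusted-initializer correlated randomness
#'
#' The trusted initializer (TI) pre-distributes all correlated randomness the
#' online protocols will consume — Beaver multiplication triples over the ring
#' and over \eqn{Z_2}, matrix triples for the two matrix products of each
#' training iteration, and masked bit pairs for bit-to-ring conversion — and
#' then plays no further part. Streams are generated up front from a plan and
#' consumed strictly in order; running past the end raises an explicit
#' depletion error, never a silent reuse.
#'
#' @param plan A randomness plan as returned by [randomness_plan()] or built
#'   by hand: a list with `matrix_triples` (list of `c(n, k, m)` dims in
#'   consumption order), `elem_triples`, `bit_triples` and `masked_bits`
#'   (counts).
#' @param fmt An [fp_format()].
#' @param seed Integer seed; the whole stream is a deterministic function of
#'   it.
#' @return An environment of class `ti_randomness` holding both parties'
#'   streams and consumption cursors.
#' @export
ti_gen <- function(plan, fmt, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lam <- fmt$lam
  r <- new.env(parent = emptyenv())
  class(r) <- "ti_randomness"

  r$mt <- lapply(plan$matrix_triples %||% list(), function(d) {
    d <- as.integer(d)
    u <- rs_rand(d[1] * d[2], lam); dim(u) <- d[1:2]
    v <- rs_rand(d[2] * d[3], lam); dim(v) <- d[2:3]
    w <- rs_matmul(u, v, lam)
    su <- share_secret(u, lam); sv <- share_secret(v, lam); sw <- share_secret(w, lam)
    list(dims = d, u = su, v = sv, w = sw)
  })
  r$mt_cursor <- 0L

  net <- as.integer(plan$elem_triples %||% 0)
  if (net > 0) {
    u <- rs_rand(net, lam); v <- rs_rand(net, lam); w <- rs_mul(u, v, lam)
    su <- share_secret(u, lam); sv <- share_secret(v, lam); sw <- share_secret(w, lam)
    r$et <- list(uA = su$alice, uB = su$bob, vA = sv$alice, vB = sv$bob,
                 wA = sw$alice, wB = sw$bob)
  } else {
    r$et <- list(uA = numeric(0), uB = numeric(0), vA = numeric(0),
                 vB = numeric(0), wA = numeric(0), wB = numeric(0))
  }
  r$et_cursor <- 0L

  nbt <- as.integer(plan$bit_triples %||% 0)
  if (nbt > 0) {
    u <- as.numeric(stats::runif(nbt) < 0.5)
    v <- as.numeric(stats::runif(nbt) < 0.5)
    w <- u * v
    su <- share_secret(u, 1L); sv <- share_secret(v, 1L); sw <- share_secret(w, 1L)
    r$bt <- list(uA = su$alice, uB = su$bob, vA = sv$alice, vB = sv$bob,
                 wA = sw$alice, wB = sw$bob)
  } else {
    r$bt <- list(uA = numeric(0), uB = numeric(0), vA = numeric(0),
                 vB = numeric(0), wA = numeric(0), wB = numeric(0))
  }
  r$bt_cursor <- 0L

  nmb <- as.integer(plan$masked_bits %||% 0)
  if (nmb > 0) {
    bit <- as.numeric(stats::runif(nmb) < 0.5)
    s2 <- share_secret(bit, 1L)
    sR <- share_secret(rs_from_signed(bit, lam), lam)
    r$mb <- list(r2A = s2$alice, r2B = s2$bob, rRA = sR$alice, rRB = sR$bob)
  } else {
    r$mb <- list(r2A = numeric(0), r2B = numeric(0), rRA = numeric(0), rRB = numeric(0))
  }
  r$mb_cursor <- 0L
  r
}

#' @export
print.ti_randomness <- function(x, ...) {
  cat(sprintf("<ti_randomness> %d matrix triple(s), %d ring triples, %d bit triples, %d masked bits\n",
              length(x$mt), length(x$et$uA), length(x$bt$uA), length(x$mb$r2A)))
  cat(sprintf("  consumed: %d / %d / %d / %d\n",
              x$mt_cursor, x$et_cursor, x$bt_cursor, x$mb_cursor))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gate counts of one bit-decomposition instance over k positions
decomp_and_gates <- function(k, variant) {
  if (k <= 1) return(0)
  K <- k - 1
  if (variant == "ripple") return(K + (K - 1))      # g layer + sequential carries
  s <- 1; total <- K                                # g layer
  while (s < K) { total <- total + 2 * (K - s); s <- 2 * s }
  total
}

decomp_rounds <- function(k, variant) {
  if (k <= 1) return(0L)
  K <- k - 1
  if (variant == "ripple") return(as.integer(1L + (K - 1L)))
  as.integer(1L + ceiling(log2(K)))
}

or_tree_gates <- function(b) max(b - 1, 0)
or_tree_rounds <- function(b) if (b <= 1) 0L else as.integer(ceiling(log2(b)))

#' Closed-form tally of secure multiplications for a training job
#'
#' Counts, phase by phase, the ring multiplications, \eqn{Z_2} AND gates,
#' masked bit pairs and Beaver triples one full training run consumes, as a
#' deterministic function of the public dimensions: sample count `n`, feature
#' count `m` (before the bias column), iteration count, fixed-point format and
#' decomposition variant. The phases mirror the protocol: the forward inner
#' products, the activation's partial bit decomposition, its OR tree over the
#' integer bits, its two bit-to-ring conversions, its two masking
#' multiplications, and the gradient matrix product.
#'
#' @param n,m Samples and features (the bias column is added internally).
#' @param n_iter Number of gradient-descent iterations.
#' @param fmt An [fp_format()].
#' @param variant `"ripple"` or `"lookahead"`.
#' @return A tibble with one row per phase plus a `total` row.
#' @export
count_secure_multiplications <- function(n, m, n_iter, fmt = fp_format(),
                                         variant = c("ripple", "lookahead")) {
  variant <- match.arg(variant)
  m1 <- m + 1
  k <- fmt$a + fmt$b + 1L
  per <- tibble::tibble(
    phase = c("inner_product", "activation_decompose", "activation_or",
              "activation_convert", "activation_mul", "gradient"),
    ring_mults = c(n * m1, 0, 0, 0, 2 * n, m1 * n),
    and_gates = c(0, n * decomp_and_gates(k, variant), n * or_tree_gates(fmt$b), 0, 0, 0),
    masked_bits = c(0, 0, 0, 2 * n, 0, 0),
    matrix_triples = c(1, 0, 0, 0, 0, 0) + c(0, 0, 0, 0, 0, 1),
    elem_triples = c(0, 0, 0, 0, 2 * n, 0))
  out <- dplyr::mutate(per, dplyr::across(-phase, ~ .x * n_iter))
  total <- dplyr::summarise(out, phase = "total",
                            dplyr::across(-phase, sum))
  dplyr::bind_rows(out, total)
}

#' Randomness plan sized for one secure training run
#'
#' Derives, from the closed-form tally, exactly the correlated randomness the
#' training protocol will request: the ordered matrix-triple shapes (forward
#' product then gradient product, per iteration) and the pooled counts of
#' elementwise ring triples, \eqn{Z_2} triples and masked bit pairs.
#'
#' @inheritParams count_secure_multiplications
#' @param slack Multiplier (> 1 pads the pooled streams; default 1, exact).
#' @return A plan list for [ti_gen()].
#' @export
randomness_plan <- function(n, m, n_iter, fmt = fp_format(),
                            variant = c("ripple", "lookahead"), slack = 1) {
  variant <- match.arg(variant)
  m1 <- as.integer(m + 1)
  n <- as.integer(n)
  tally <- count_secure_multiplications(n, m, n_iter, fmt, variant)
  tot <- tally[tally$phase == "total", ]
  mt <- vector("list", 2L * n_iter)
  if (n_iter > 0) {
    for (i in seq_len(n_iter)) {
      mt[[2L * i - 1L]] <- c(n, m1, 1L)
      mt[[2L * i]] <- c(m1, n, 1L)
    }
  }
  list(matrix_triples = mt,
       elem_triples = ceiling(tot$elem_triples * slack),
       bit_triples = ceiling(tot$and_gates * slack),
       masked_bits = ceiling(tot$masked_bits * slack))
}
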