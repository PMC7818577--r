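#' Instrumented two-party channel and protocol session
#'
#' An `mpc_session` bundles everything one execution of the online protocols
#' needs: the fixed-point format, the instrumented channel counters (rounds,
#' messages, bytes and the per-exchange transcript), the correlated-randomness
#' streams received from the trusted initializer, and running tallies of
#' consumed multiplications per protocol phase.
#'
#' A *round* is one simultaneous bidirectional exchange: every open of one or
#' more independent values issued together costs exactly one round, whatever
#' the payload size. \eqn{Z_2} messages are accounted as bit-packed words of
#' `lam` bits each.
#'
#' @param fmt An [fp_format()].
#' @param randomness Correlated randomness from [ti_gen()]; `NULL` gives a
#'   session that only supports local operations.
#' @param variant Bit-decomposition circuit: `"ripple"` (linear rounds) or
#'   `"lookahead"` (logarithmic rounds).
#' @return An environment of class `mpc_session`.
#' @export
mpc_session <- function(fmt, randomness = NULL, variant = c("ripple", "lookahead")) {
  variant <- match.arg(variant)
  ctx <- new.env(parent = emptyenv())
  ctx$fmt <- fmt
  ctx$variant <- variant
  ctx$rounds <- 0L
  ctx$messages <- 0L
  ctx$bytes_a2b <- 0
  ctx$bytes_b2a <- 0
  ctx$transcript <- list()
  ctx$phase <- "unphased"
  ctx$tally <- list()
  ctx$rand <- randomness
  ctx$trunc_record <- NULL
  class(ctx) <- "mpc_session"
  ctx
}

#' @export
print.mpc_session <- function(x, ...) {
  cat(sprintf("<mpc_session> lambda = %d, variant = %s | %d rounds, %d messages, %.0f bytes/direction\n",
              x$fmt$lam, x$variant, x$rounds, x$messages, x$bytes_a2b))
  invisible(x)
}

# bytes one direction would send to open the payloads (Z_2 packed into
# lam-bit words along the batch axis)
payload_bytes <- function(payloads, lam) {
  sum(vapply(payloads, function(p) {
    n <- st_len(p)
    if (p$mod_bits == 1L) ceiling(n / lam) * (lam / 8) else n * (lam / 8)
  }, numeric(1)))
}

# One simultaneous exchange opening a list of shared tensors: both parties
# send their shares of every payload in the same round.
ch_exchange <- function(ctx, payloads) {
  bytes <- payload_bytes(payloads, ctx$fmt$lam)
  ctx$rounds <- ctx$rounds + 1L
  ctx$messages <- ctx$messages + 2L
  ctx$bytes_a2b <- ctx$bytes_a2b + bytes
  ctx$bytes_b2a <- ctx$bytes_b2a + bytes
  ctx$transcript[[length(ctx$transcript) + 1L]] <- c(a2b = bytes, b2a = bytes)
  lapply(payloads, reconstruct)
}

# phase bookkeeping ----------------------------------------------------------

set_phase <- function(ctx, phase) {
  ctx$phase <- phase
  invisible(ctx)
}

tally_add <- function(ctx, what, n) {
  ph <- ctx$tally[[ctx$phase]]
  if (is.null(ph)) ph <- c(ring_mults = 0, and_gates = 0, masked_bits = 0,
                           matrix_triples = 0, elem_triples = 0)
  ph[[what]] <- ph[[what]] + n
  ctx$tally[[ctx$phase]] <- ph
  invisible(ctx)
}

#' Summarize a session's consumption and traffic
#'
#' @param ctx An [mpc_session()].
#' @return A tibble with one row per protocol phase and columns for ring
#'   multiplications, Z_2 AND gates, masked bits and triples consumed.
#' @export
session_tally <- function(ctx) {
  if (length(ctx$tally) == 0) {
    return(tibble::tibble(phase = character(), ring_mults = numeric(),
                          and_gates = numeric(), masked_bits = numeric(),
                          matrix_triples = numeric(), elem_triples = numeric()))
  }
  purrr::imap_dfr(ctx$tally, function(v, nm) {
    tibble::tibble(phase = nm, ring_mults = v[["ring_mults"]],
                   and_gates = v[["and_gates"]], masked_bits = v[["masked_bits"]],
                   matrix_triples = v[["matrix_triples"]],
                   elem_triples = v[["elem_triples"]])
  })
}

# correlated randomness consumption ------------------------------------------

take_matrix_triple <- function(ctx, dims) {
  r <- ctx$rand
  if (is.null(r)) stop("session has no correlated randomness attached")
  i <- r$mt_cursor + 1L
  if (i > length(r$mt)) stop("correlated randomness depleted: no matrix triple left")
  tr <- r$mt[[i]]
  if (!identical(tr$dims, as.integer(dims)))
    stop(sprintf("matrix triple shape mismatch: have (%s), need (%s)",
                 paste(tr$dims, collapse = ","), paste(dims, collapse = ",")))
  r$mt_cursor <- i
  tr
}

take_elem_triples <- function(ctx, n) {
  r <- ctx$rand
  if (is.null(r)) stop("session has no correlated randomness attached")
  i <- r$et_cursor
  if (i + n > length(r$et$uA))
    stop("correlated randomness depleted: ring multiplication triples exhausted")
  idx <- (i + 1L):(i + n)
  r$et_cursor <- i + n
  list(u = st_new(r$et$uA[idx], r$et$uB[idx], ctx$fmt$lam),
       v = st_new(r$et$vA[idx], r$et$vB[idx], ctx$fmt$lam),
       w = st_new(r$et$wA[idx], r$et$wB[idx], ctx$fmt$lam))
}

take_bit_triples <- function(ctx, n) {
  r <- ctx$rand
  if (is.null(r)) stop("session has no correlated randomness attached")
  i <- r$bt_cursor
  if (i + n > length(r$bt$uA))
    stop("correlated randomness depleted: Z_2 multiplication triples exhausted")
  idx <- (i + 1L):(i + n)
  r$bt_cursor <- i + n
  list(u = st_new(r$bt$uA[idx], r$bt$uB[idx], 1L),
       v = st_new(r$bt$vA[idx], r$bt$vB[idx], 1L),
       w = st_new(r$bt$wA[idx], r$bt$wB[idx], 1L))
}

take_masked_bits <- function(ctx, n) {
  r <- ctx$rand
  if (is.null(r)) stop("session has no correlated randomness attached")
  i <- r$mb_cursor
  if (i + n > length(r$mb$r2A))
    stop("correlated randomness depleted: masked bit pairs exhausted")
  idx <- (i + 1L):(i + n)
  r$mb_cursor <- i + n
  list(r_bit = st_new(r$mb$r2A[idx], r$mb$r2B[idx], 1L),
       r_ring = st_new(r$mb$rRA[idx], r$mb$rRB[idx], ctx$fmt$lam))
}

# truncation-event recording (strong oracle support) --------------------------

record_trunc <- function(ctx, p) {
  if (is.null(ctx$trunc_record)) return(invisible(NULL))
  rec <- ctx$trunc_record
  rec$splits[[length(rec$splits) + 1L]] <- as.numeric(p$alice)
  invisible(NULL)
}

start_trunc_recording <- function(ctx) {
  ctx$trunc_record <- new.env(parent = emptyenv())
  ctx$trunc_record$splits <- list()
  invisible(ctx)
}
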