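#' Fixed-point format over \eqn{Z_{2^\lambda}}
#'
#' Describes the two's-complement fixed-point register map used to carry real
#' values in the ring \eqn{Z_{2^\lambda}}: the lowest `frac_bits` bits hold the
#' fractional part, the next `int_bits` bits the integer part, and every bit
#' above position `frac_bits + int_bits` replicates the sign. A real value
#' \eqn{x} is representable when \eqn{|x| < 2^{int\_bits}}.
#'
#' The ring size must satisfy `ring_bits >= 2 * (frac_bits + int_bits)` so
#' that a single product of two encoded values (which lives on scale
#' \eqn{2^{2a}}) still fits before truncation. `ring_bits` is restricted to
#' machine word widths; the small widths exist for exhaustive testing.
#'
#' @param frac_bits Number of fractional bits \eqn{a} (default 12).
#' @param int_bits Number of integer bits \eqn{b} (default 15).
#' @param ring_bits Total ring bits \eqn{\lambda}; one of 8, 16, 32, 64
#'   (default 64).
#' @return An object of class `fp_format` with fields `a`, `b`, `lam`.
#' @examples
#' fmt <- fp_format()
#' fp_decode(fp_encode(c(-1.5, 0.25), fmt), fmt)
#' @export
fp_format <- function(frac_bits = 12, int_bits = 15, ring_bits = 64) {
  a <- as.integer(frac_bits)
  b <- as.integer(int_bits)
  lam <- as.integer(ring_bits)
  if (a < 1L) stop("frac_bits must be >= 1")
  if (b < 1L) stop("int_bits must be >= 1")
  if (!lam %in% c(8L, 16L, 32L, 64L))
    stop("ring_bits must be one of 8, 16, 32, 64")
  if (lam < 2L * (a + b))
    stop("ring_bits must be at least 2 * (frac_bits + int_bits)")
  structure(list(a = a, b = b, lam = lam), class = "fp_format")
}

#' @export
print.fp_format <- function(x, ...) {
  cat(sprintf(
    "<fp_format> a = %d fractional bits, b = %d integer bits, lambda = %d (q = 2^%d)\n",
    x$a, x$b, x$lam, x$lam))
  invisible(x)
}

#' Encode real values into the fixed-point ring
#'
#' Maps each real \eqn{x} to \eqn{Q(x) = \lfloor 2^a x \rfloor} for
#' \eqn{x \ge 0} and \eqn{2^\lambda - \lfloor 2^a |x| \rfloor} for
#' \eqn{x < 0} (truncation toward zero on the magnitude, two's-complement
#' sign). Errors if any \eqn{|x| \ge 2^b}.
#'
#' @param x Numeric vector or matrix of reals with \eqn{|x| < 2^b}.
#' @param fmt An [fp_format()].
#' @return Ring elements (opaque pattern doubles) with the shape of `x`.
#' @export
fp_encode <- function(x, fmt) {
  out <- rs_encode(as.numeric(x), fmt$a, fmt$b, fmt$lam)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Decode fixed-point ring elements back to reals
#'
#' Inverse of [fp_encode()] under the register map: interprets each ring
#' element as a two's-complement fixed-point number on scale \eqn{2^{-a}}.
#' With `check = TRUE` (default) a ring element outside the representable
#' window \eqn{|x| < 2^b} raises an error.
#'
#' @param v Ring elements as produced by [fp_encode()] or by opening shares.
#' @param fmt An [fp_format()].
#' @param check Enforce the representable-window precondition.
#' @return Numeric vector/matrix of decoded reals.
#' @export
fp_decode <- function(v, fmt, check = TRUE) {
  out <- rs_decode(as.numeric(v), fmt$a, fmt$b, fmt$lam, check)
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

#' Modular ring arithmetic in \eqn{Z_{2^\lambda}}
#'
#' Exact arithmetic modulo \eqn{2^\lambda} on ring elements; results always
#' wrap around, never signal overflow. Length-1 operands recycle.
#'
#' @param u,v Ring elements.
#' @param fmt An [fp_format()] supplying \eqn{\lambda}.
#' @return Ring elements.
#' @name ring-ops
NULL

#' @rdname ring-ops
#' @export
ring_add <- function(u, v, fmt) keep_dim(rs_add(as.numeric(u), as.numeric(v), fmt$lam), u, v)

#' @rdname ring-ops
#' @export
ring_sub <- function(u, v, fmt) keep_dim(rs_sub(as.numeric(u), as.numeric(v), fmt$lam), u, v)

#' @rdname ring-ops
#' @export
ring_mul <- function(u, v, fmt) keep_dim(rs_mul(as.numeric(u), as.numeric(v), fmt$lam), u, v)

#' @rdname ring-ops
#' @param c A scalar ring element (e.g. an encoded public constant).
#' @export
ring_scale <- function(c, u, fmt) keep_dim(rs_mul(as.numeric(u), as.numeric(c), fmt$lam), u, u)

#' Convert between ring elements and plain integers
#'
#' `ring_from_int()` maps signed integer-valued doubles into
#' \eqn{Z_{2^\lambda}} (two's complement); `ring_to_int()` is the signed
#' inverse and `ring_to_uint()` the unsigned one. Both inverses error if the
#' result is not exactly representable in a double (magnitude \eqn{\ge 2^{53}}).
#'
#' @param x Integer-valued numeric vector.
#' @inheritParams ring-ops
#' @return Ring elements, or plain numeric for the inverses.
#' @export
ring_from_int <- function(x, fmt) {
  out <- rs_from_signed(as.numeric(x), fmt$lam)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' @rdname ring_from_int
#' @export
ring_to_int <- function(u, fmt) {
  out <- rs_to_signed(as.numeric(u), fmt$lam)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}

#' @rdname ring_from_int
#' @export
ring_to_uint <- function(u, fmt) {
  out <- rs_to_unsigned(as.numeric(u), fmt$lam)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}

#' Render ring elements as fixed-width hex strings
#' @inheritParams ring-ops
#' @return Character vector of zero-padded hex words.
#' @export
ring_hex <- function(u, fmt) rs_hex(as.numeric(u), fmt$lam)

#' Bitwise equality of ring elements
#' @inheritParams ring-ops
#' @return Logical vector.
#' @export
ring_eq <- function(u, v, fmt) rs_eq(as.numeric(u), as.numeric(v))

# preserve matrix shape through elementwise C++ calls
keep_dim <- function(out, u, v) {
  d <- if (!is.null(dim(u))) dim(u) else dim(v)
  if (!is.null(d) && length(out) == prod(d)) dim(out) <- d
  out
}
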