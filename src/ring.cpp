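// Exact arithmetic in Z_{2^lambda} for lambda in {8, 16, 32, 64}.
//
// Ring elements travel through R as doubles whose 64-bit IEEE pattern *is*
// the uint64 ring value (same storage trick as the bit64 package). R code
// must never apply numeric arithmetic or comparison to these doubles; every
// operation goes through the functions below, which reinterpret via memcpy.

#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t d2u(double x) {
  uint64_t u;
  std::memcpy(&u, &x, 8);
  return u;
}

static inline double u2d(uint64_t u) {
  double x;
  std::memcpy(&x, &u, 8);
  return x;
}

static inline uint64_t ring_mask(int lam) {
  if (lam < 1 || lam > 64) stop("ring_bits must lie in [1, 64]");
  return (lam == 64) ? ~UINT64_C(0) : ((UINT64_C(1) << lam) - 1);
}

// recycle a length-1 operand against a longer one
static inline R_xlen_t out_len(R_xlen_t nx, R_xlen_t ny) {
  if (nx == ny) return nx;
  if (nx == 1) return ny;
  if (ny == 1) return nx;
  stop("operand lengths %d and %d are not conformable", (int)nx, (int)ny);
}

// [[Rcpp::export]]
NumericVector rs_add(NumericVector x, NumericVector y, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = out_len(x.size(), y.size());
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t a = d2u(x[x.size() == 1 ? 0 : i]);
    uint64_t b = d2u(y[y.size() == 1 ? 0 : i]);
    z[i] = u2d((a + b) & m);
  }
  return z;
}

// [[Rcpp::export]]
NumericVector rs_sub(NumericVector x, NumericVector y, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = out_len(x.size(), y.size());
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t a = d2u(x[x.size() == 1 ? 0 : i]);
    uint64_t b = d2u(y[y.size() == 1 ? 0 : i]);
    z[i] = u2d((a - b) & m);
  }
  return z;
}

// [[Rcpp::export]]
NumericVector rs_neg(NumericVector x, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = x.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) z[i] = u2d((~d2u(x[i]) + 1) & m);
  return z;
}

// [[Rcpp::export]]
NumericVector rs_mul(NumericVector x, NumericVector y, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = out_len(x.size(), y.size());
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t a = d2u(x[x.size() == 1 ? 0 : i]);
    uint64_t b = d2u(y[y.size() == 1 ? 0 : i]);
    z[i] = u2d((a * b) & m);
  }
  return z;
}

// [[Rcpp::export]]
NumericMatrix rs_matmul(NumericMatrix a, NumericMatrix b, int lam) {
  uint64_t m = ring_mask(lam);
  int nr = a.nrow(), k = a.ncol(), nc = b.ncol();
  if (b.nrow() != k) stop("matrix dimensions are not conformable");
  NumericMatrix z(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      uint64_t acc = 0;
      for (int t = 0; t < k; ++t) acc += d2u(a(i, t)) * d2u(b(t, j));
      z(i, j) = u2d(acc & m);
    }
  }
  return z;
}

// Q(x) = floor(2^a * x) for x >= 0, 2^lam - floor(2^a * |x|) for x < 0.
// [[Rcpp::export]]
NumericVector rs_encode(NumericVector x, int a, int b, int lam) {
  uint64_t m = ring_mask(lam);
  double bound = std::ldexp(1.0, b);
  R_xlen_t n = x.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (!R_finite(v) || std::fabs(v) >= bound)
      stop("value %g is not representable: |x| must be < 2^%d", v, b);
    uint64_t mag = (uint64_t) std::floor(std::ldexp(std::fabs(v), a));
    z[i] = u2d((v < 0 ? (~mag + 1) : mag) & m);
  }
  return z;
}

// Two's-complement interpretation within lambda bits, rescaled by 2^-a.
// check = TRUE enforces that the value lies in the representable window
// (all bits above position a+b replicate the sign bit).
// [[Rcpp::export]]
NumericVector rs_decode(NumericVector v, int a, int b, int lam, bool check) {
  uint64_t m = ring_mask(lam);
  uint64_t half = (lam == 64) ? (UINT64_C(1) << 63) : (UINT64_C(1) << (lam - 1));
  uint64_t win = UINT64_C(1) << (a + b);  // a+b < 64 always (lam >= 2(a+b))
  R_xlen_t n = v.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(v[i]) & m;
    bool neg = (u & half) != 0;
    uint64_t mag = neg ? ((~u + 1) & m) : u;
    if (check && mag >= win)
      stop("ring value outside the representable window |x| < 2^%d", b);
    z[i] = std::ldexp((double) mag, -a) * (neg ? -1.0 : 1.0);
  }
  return z;
}

// signed double integers (|x| < 2^53) -> ring patterns mod 2^lam
// [[Rcpp::export]]
NumericVector rs_from_signed(NumericVector x, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = x.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (!R_finite(v) || std::fabs(v) >= 9007199254740992.0 || v != std::floor(v))
      stop("rs_from_signed needs integer-valued doubles with |x| < 2^53");
    int64_t s = (int64_t) v;
    z[i] = u2d(((uint64_t) s) & m);
  }
  return z;
}

// ring pattern -> signed two's-complement value as double (error if not exact)
// [[Rcpp::export]]
NumericVector rs_to_signed(NumericVector v, int lam) {
  uint64_t m = ring_mask(lam);
  uint64_t half = (lam == 64) ? (UINT64_C(1) << 63) : (UINT64_C(1) << (lam - 1));
  R_xlen_t n = v.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(v[i]) & m;
    bool neg = (u & half) != 0;
    uint64_t mag = neg ? ((~u + 1) & m) : u;
    if (mag >= UINT64_C(9007199254740992))
      stop("ring value magnitude exceeds 2^53; not exactly representable");
    z[i] = neg ? -((double) mag) : (double) mag;
  }
  return z;
}

// ring pattern -> unsigned value as double (error if >= 2^53)
// [[Rcpp::export]]
NumericVector rs_to_unsigned(NumericVector v, int lam) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = v.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(v[i]) & m;
    if (u >= UINT64_C(9007199254740992))
      stop("ring value exceeds 2^53; not exactly representable");
    z[i] = (double) u;
  }
  return z;
}

// uniform draws from Z_{2^lam}, consuming R's RNG stream (seedable via set.seed)
// [[Rcpp::export]]
NumericVector rs_rand(int n, int lam) {
  uint64_t m = ring_mask(lam);
  NumericVector z(n);
  for (int i = 0; i < n; ++i) {
    uint64_t hi = (uint64_t) R_unif_index(4294967296.0);
    uint64_t lo = (uint64_t) R_unif_index(4294967296.0);
    z[i] = u2d(((hi << 32) | lo) & m);
  }
  return z;
}

// local truncation by d bits: party 0 (Alice) maps her share to
// floor(share / 2^d); party 1 (Bob) to -floor((q - share)/2^d) mod q.
// [[Rcpp::export]]
NumericVector rs_trunc(NumericVector x, int d, int lam, int party) {
  uint64_t m = ring_mask(lam);
  R_xlen_t n = x.size();
  NumericVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(x[i]) & m;
    if (party == 0) {
      z[i] = u2d((u >> d) & m);
    } else {
      uint64_t neg = (~u + 1) & m;         // q - share mod q
      z[i] = u2d((~(neg >> d) + 1) & m);   // q - floor(.)/2^d mod q
    }
  }
  return z;
}

// low-k bits of each element as an ordinary 0/1 numeric matrix (n x k),
// column j = bit position j (1 = least significant)
// [[Rcpp::export]]
NumericMatrix rs_bits(NumericVector x, int k, int lam) {
  if (k < 1 || k > lam) stop("bit positions k must lie in [1, ring_bits]");
  uint64_t m = ring_mask(lam);
  R_xlen_t n = x.size();
  NumericMatrix z(n, k);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t u = d2u(x[i]) & m;
    for (int j = 0; j < k; ++j) z(i, j) = (double) ((u >> j) & 1);
  }
  return z;
}

// recompose 0/1 bit matrix (n x k, column j = bit j) into ring patterns
// [[Rcpp::export]]
NumericVector rs_from_bits(NumericMatrix bits, int lam) {
  uint64_t m = ring_mask(lam);
  int n = bits.nrow(), k = bits.ncol();
  NumericVector z(n);
  for (int i = 0; i < n; ++i) {
    uint64_t u = 0;
    for (int j = 0; j < k; ++j)
      if (bits(i, j) != 0) u |= (UINT64_C(1) << j);
    z[i] = u2d(u & m);
  }
  return z;
}

// [[Rcpp::export]]
LogicalVector rs_eq(NumericVector x, NumericVector y) {
  R_xlen_t n = out_len(x.size(), y.size());
  LogicalVector z(n);
  for (R_xlen_t i = 0; i < n; ++i)
    z[i] = d2u(x[x.size() == 1 ? 0 : i]) == d2u(y[y.size() == 1 ? 0 : i]);
  return z;
}

// [[Rcpp::export]]
CharacterVector rs_hex(NumericVector x, int lam) {
  R_xlen_t n = x.size();
  CharacterVector z(n);
  char buf[32];
  int width = (lam + 3) / 4;
  for (R_xlen_t i = 0; i < n; ++i) {
    snprintf(buf, sizeof(buf), "%0*llx", width,
             (unsigned long long) (d2u(x[i]) & ring_mask(lam)));
    z[i] = buf;
  }
  return z;
}
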