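#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact rational arithmetic kernel.
//
// Numerators and denominators travel between R and C++ as doubles holding
// exact integers (|x| <= 2^53). All intermediate products/sums are taken in
// __int128, which comfortably holds the cross-products of two 53-bit
// operands (<= 2^107 < 2^127). Every result is reduced to lowest terms with
// a positive denominator; a reduced component that no longer fits in 2^53
// raises an error rather than losing exactness silently.

typedef __int128 int128;

static const double MAX_EXACT = 9007199254740992.0; // 2^53

static int128 to_i128(double x) {
  if (!R_finite(x) || x != std::floor(x) || std::fabs(x) > MAX_EXACT)
    stop("rational component is not an exactly representable integer (|x| <= 2^53)");
  return (int128)x;
}

static int128 gcd128(int128 a, int128 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b != 0) { int128 t = a % b; a = b; b = t; }
  return a;
}

static void reduce(int128 &n, int128 &d) {
  if (d == 0) stop("rational with zero denominator");
  if (d < 0) { n = -n; d = -d; }
  if (n == 0) { d = 1; return; }
  int128 g = gcd128(n, d);
  n /= g; d /= g;
}

static double back(int128 v) {
  if (v > (int128)MAX_EXACT || v < -(int128)MAX_EXACT)
    stop("rational overflow: reduced numerator or denominator exceeds 2^53");
  return (double)v;
}

// [[Rcpp::export(name = ".rat_norm")]]
List rat_norm(NumericVector num, NumericVector den) {
  R_xlen_t n = num.size();
  if (den.size() != n) stop("numerator and denominator lengths differ");
  NumericVector on(n), od(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int128 a = to_i128(num[i]), b = to_i128(den[i]);
    reduce(a, b);
    on[i] = back(a); od[i] = back(b);
  }
  return List::create(_["num"] = on, _["den"] = od);
}

// op: 1 add, 2 subtract, 3 multiply, 4 divide
// [[Rcpp::export(name = ".rat_arith")]]
List rat_arith(NumericVector an, NumericVector ad,
               NumericVector bn, NumericVector bd, int op) {
  R_xlen_t n = an.size();
  if (ad.size() != n || bn.size() != n || bd.size() != n)
    stop("operand lengths differ");
  NumericVector on(n), od(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int128 p = to_i128(an[i]), q = to_i128(ad[i]);
    int128 r = to_i128(bn[i]), s = to_i128(bd[i]);
    int128 num, den;
    switch (op) {
    case 1: num = p * s + r * q; den = q * s; break;
    case 2: num = p * s - r * q; den = q * s; break;
    case 3: num = p * r;         den = q * s; break;
    case 4:
      if (r == 0) stop("rational division by zero");
      num = p * s; den = q * r; break;
    default: stop("unknown operation code");
    }
    reduce(num, den);
    on[i] = back(num); od[i] = back(den);
  }
  return List::create(_["num"] = on, _["den"] = od);
}

// sign of a - b, elementwise: -1, 0, 1
// [[Rcpp::export(name = ".rat_cmp")]]
IntegerVector rat_cmp(NumericVector an, NumericVector ad,
                      NumericVector bn, NumericVector bd) {
  R_xlen_t n = an.size();
  if (ad.size() != n || bn.size() != n || bd.size() != n)
    stop("operand lengths differ");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    // denominators are positive after normalisation, so cross-products order
    int128 lhs = to_i128(an[i]) * to_i128(bd[i]);
    int128 rhs = to_i128(bn[i]) * to_i128(ad[i]);
    out[i] = (lhs > rhs) - (lhs < rhs);
  }
  return out;
}

// exact sum of a rational vector, reducing after each step
// [[Rcpp::export(name = ".rat_sum")]]
List rat_sum(NumericVector num, NumericVector den) {
  R_xlen_t n = num.size();
  int128 sn = 0, sd = 1;
  for (R_xlen_t i = 0; i < n; ++i) {
    int128 a = to_i128(num[i]), b = to_i128(den[i]);
    int128 nn = sn * b + a * sd, nd = sd * b;
    reduce(nn, nd);
    sn = nn; sd = nd;
  }
  return List::create(_["num"] = NumericVector::create(back(sn)),
                      _["den"] = NumericVector::create(back(sd)));
}
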