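// Fixed-precision binary floating point for the protein series pipeline.
//
// value = sign * (m[0] + m[1]/B + ... + m[NL-1]/B^(NL-1)) * B^e,  B = 2^32,
// with m[0] != 0 for nonzero values (limb-normalized).  Precision is a
// runtime global (number of limbs); the default ~150 decimal digits covers
// the cancellation headroom the cyclo-stationary protein series need at
// physiological parameter values, and can be raised further.
//
// Only the operations the pipeline requires are implemented: field ops,
// comparisons, sqrt, exp, and series-computed ln 2 and pi.

#ifndef CYCLOSTAT_HP_H
#define CYCLOSTAT_HP_H

#include <vector>
#include <cstdint>
#include <cmath>
#include <stdexcept>

struct HP {
  static int NL; // limbs of precision (>= 4); set via setPrecision()

  int sign = 0;
  long long e = 0;
  std::vector<uint32_t> m;

  HP() {}
  HP(double x) { *this = fromDouble(x); }
  HP(int x) { *this = fromDouble((double)x); }
  HP(long long x) { *this = fromDouble((double)x); }

  static void setPrecision(int limbs);
  static int decimalDigits();

  static HP fromDouble(double x);
  static HP pow2(long long k); // exact 2^k
  double toDouble() const;
  double log2abs() const; // log2 |x| (for magnitude bookkeeping)

  bool isZero() const { return sign == 0; }

  HP operator-() const {
    HP r = *this;
    r.sign = -r.sign;
    return r;
  }
  HP operator+(const HP &b) const;
  HP operator-(const HP &b) const { return *this + (-b); }
  HP operator*(const HP &b) const;
  HP operator/(const HP &b) const { return *this * recip(b); }
  HP &operator+=(const HP &b) { return *this = *this + b; }
  HP &operator-=(const HP &b) { return *this = *this - b; }
  HP &operator*=(const HP &b) { return *this = *this * b; }
  HP &operator/=(const HP &b) { return *this = *this / b; }

  HP mulSmall(uint32_t v) const;  // multiply by a small integer
  HP divSmall(uint32_t v) const;  // divide by a small integer
  HP scal2(long long k) const { return *this * pow2(k); }

  static int cmpAbs(const HP &a, const HP &b); // -1, 0, 1
  bool operator<(const HP &b) const;
  bool operator>(const HP &b) const { return b < *this; }

  static HP abs(const HP &a) {
    HP r = a;
    if (r.sign) r.sign = 1;
    return r;
  }
  static HP recip(const HP &d);
  static HP sqrt(const HP &x);
  static HP exp(const HP &x);
  static HP ln(const HP &x);
  static const HP &ln2();
  static const HP &pi();
};

#endif
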