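#include "hp.h"
#include <map>

int HP::NL = 18; // ~165 decimal digits default

void HP::setPrecision(int limbs) {
  if (limbs < 4 || limbs > 80) throw std::runtime_error("bad precision");
  NL = limbs;
}
int HP::decimalDigits() { return (int)(32 * (NL - 1) * 0.30103); }

static const double B = 4294967296.0; // 2^32

HP HP::fromDouble(double x) {
  HP r;
  if (x == 0 || !std::isfinite(x)) return r;
  r.sign = x > 0 ? 1 : -1;
  double v = std::fabs(x);
  int e2;
  std::frexp(v, &e2); // v = f * 2^e2, f in [0.5, 1)
  long long e = (long long)std::floor((e2 - 1) / 32.0);
  double scaled = std::ldexp(v, (int)(-32 * e)); // in [1, B)
  r.e = e;
  r.m.assign(NL, 0);
  for (int i = 0; i < 3 && i < NL; i++) {
    double d = std::floor(scaled);
    r.m[i] = (uint32_t)d;
    scaled = (scaled - d) * B;
  }
  if (r.m[0] == 0) { // can happen at binade edges; renormalize
    int z = 0;
    while (z < NL && r.m[z] == 0) z++;
    if (z == NL) { r.sign = 0; r.e = 0; return r; }
    for (int i = 0; i + z < NL; i++) r.m[i] = r.m[i + z];
    for (int i = NL - z; i < NL; i++) r.m[i] = 0;
    r.e -= z;
  }
  return r;
}

HP HP::pow2(long long k) {
  HP r;
  r.sign = 1;
  long long q = (k >= 0) ? k / 32 : -(((-k) + 31) / 32);
  int rbits = (int)(k - 32 * q); // 0..31
  r.e = q;
  r.m.assign(NL, 0);
  r.m[0] = (uint32_t)1u << rbits;
  return r;
}

double HP::toDouble() const {
  if (sign == 0) return 0.0;
  double v = 0;
  for (int i = std::min(3, NL) - 1; i >= 0; i--) v = v / B + (double)m[i];
  // v in [1, B); value = v * B^e
  if (e > 32) return sign > 0 ? INFINITY : -INFINITY;
  if (e < -40) return 0.0;
  return sign * std::ldexp(v, (int)(32 * e));
}

double HP::log2abs() const {
  if (sign == 0) return -INFINITY;
  double v = 0;
  for (int i = std::min(3, NL) - 1; i >= 0; i--) v = v / B + (double)m[i];
  return std::log2(v) + 32.0 * (double)e;
}

int HP::cmpAbs(const HP &a, const HP &b) {
  if (a.sign == 0) return b.sign == 0 ? 0 : -1;
  if (b.sign == 0) return 1;
  if (a.e != b.e) return a.e > b.e ? 1 : -1;
  for (int i = 0; i < NL; i++)
    if (a.m[i] != b.m[i]) return a.m[i] > b.m[i] ? 1 : -1;
  return 0;
}

bool HP::operator<(const HP &b) const {
  if (sign != b.sign) return sign < b.sign;
  int c = cmpAbs(*this, b);
  return sign >= 0 ? c < 0 : c > 0;
}

// |a| >= |b| assumed; same-sign magnitude add
static HP addAbs(const HP &a, const HP &b) {
  long long d = a.e - b.e;
  if (d >= HP::NL) return a;
  HP r;
  r.sign = a.sign;
  r.e = a.e;
  r.m.assign(HP::NL, 0);
  uint64_t carry = 0;
  for (int i = HP::NL - 1; i >= 0; i--) {
    uint64_t s = (uint64_t)a.m[i] + carry;
    long long j = i - d;
    if (j >= 0 && j < HP::NL) s += b.m[j];
    r.m[i] = (uint32_t)s;
    carry = s >> 32;
  }
  if (carry) { // shift right one limb
    for (int i = HP::NL - 1; i >= 1; i--) r.m[i] = r.m[i - 1];
    r.m[0] = (uint32_t)carry;
    r.e += 1;
  }
  return r;
}

// |a| > |b| assumed
static HP subAbs(const HP &a, const HP &b) {
  long long d = a.e - b.e;
  if (d >= HP::NL) return a;
  HP r;
  r.sign = a.sign;
  r.e = a.e;
  r.m.assign(HP::NL, 0);
  int64_t borrow = 0;
  for (int i = HP::NL - 1; i >= 0; i--) {
    int64_t s = (int64_t)a.m[i] - borrow;
    long long j = i - d;
    if (j >= 0 && j < HP::NL) s -= (int64_t)b.m[j];
    if (s < 0) {
      s += (int64_t)1 << 32;
      borrow = 1;
    } else {
      borrow = 0;
    }
    r.m[i] = (uint32_t)s;
  }
  int z = 0;
  while (z < HP::NL && r.m[z] == 0) z++;
  if (z == HP::NL) {
    r.sign = 0;
    r.e = 0;
    return r;
  }
  if (z > 0) {
    for (int i = 0; i + z < HP::NL; i++) r.m[i] = r.m[i + z];
    for (int i = HP::NL - z; i < HP::NL; i++) r.m[i] = 0;
    r.e -= z;
  }
  return r;
}

HP HP::operator+(const HP &b) const {
  if (sign == 0) return b;
  if (b.sign == 0) return *this;
  if (sign == b.sign) {
    return cmpAbs(*this, b) >= 0 ? addAbs(*this, b) : addAbs(b, *this);
  }
  int c = cmpAbs(*this, b);
  if (c == 0) return HP();
  return c > 0 ? subAbs(*this, b) : subAbs(b, *this);
}

HP HP::operator*(const HP &b) const {
  HP r;
  if (sign == 0 || b.sign == 0) return r;
  int n = NL;
  int np = n + 2; // guard diagonals
  std::vector<unsigned __int128> acc(np, 0);
  for (int i = 0; i < n; i++) {
    if (m[i] == 0) continue;
    uint64_t ai = m[i];
    int jmax = std::min(n - 1, np - 1 - i);
    for (int j = 0; j <= jmax; j++)
      acc[i + j] += (unsigned __int128)(ai * (uint64_t)b.m[j]);
  }
  // carry propagation toward more significant positions
  std::vector<uint64_t> limb(np, 0);
  unsigned __int128 carry = 0;
  for (int p = np - 1; p >= 1; p--) {
    unsigned __int128 cur = acc[p] + carry;
    limb[p] = (uint64_t)(cur & 0xffffffffu);
    carry = cur >> 32;
  }
  unsigned __int128 v0 = acc[0] + carry; // in [1, B^2)
  r.sign = sign * b.sign;
  r.m.assign(n, 0);
  if (v0 >> 32) {
    r.e = e + b.e + 1;
    r.m[0] = (uint32_t)(v0 >> 32);
    for (int i = 1; i < n; i++)
      r.m[i] = (uint32_t)(i - 1 < np - 1 ? (i == 1 ? (v0 & 0xffffffffu)
                                                   : limb[i - 1])
                                         : 0);
  } else {
    r.e = e + b.e;
    r.m[0] = (uint32_t)v0;
    for (int i = 1; i < n; i++) r.m[i] = (uint32_t)(i < np ? limb[i] : 0);
  }
  return r;
}

HP HP::mulSmall(uint32_t v) const {
  if (sign == 0 || v == 0) return HP();
  if (v == 1) return *this;
  HP r;
  r.sign = sign;
  r.e = e;
  r.m.assign(NL, 0);
  uint64_t carry = 0;
  for (int i = NL - 1; i >= 0; i--) {
    uint64_t s = (uint64_t)m[i] * v + carry;
    r.m[i] = (uint32_t)s;
    carry = s >> 32;
  }
  if (carry) {
    for (int i = NL - 1; i >= 1; i--) r.m[i] = r.m[i - 1];
    r.m[0] = (uint32_t)carry;
    r.e += 1;
  }
  return r;
}

HP HP::divSmall(uint32_t v) const {
  if (v == 0) throw std::runtime_error("division by zero");
  if (sign == 0 || v == 1) return *this;
  HP r;
  r.sign = sign;
  r.e = e;
  std::vector<uint32_t> q(NL + 1, 0);
  uint64_t rem = 0;
  for (int i = 0; i <= NL; i++) {
    uint64_t cur = (rem << 32) | (i < NL ? m[i] : 0);
    q[i] = (uint32_t)(cur / v);
    rem = cur % v;
  }
  r.m.assign(NL, 0);
  if (q[0] == 0) {
    for (int i = 0; i < NL; i++) r.m[i] = q[i + 1];
    r.e -= 1;
  } else {
    for (int i = 0; i < NL; i++) r.m[i] = q[i];
  }
  return r;
}

HP HP::recip(const HP &d) {
  if (d.sign == 0) throw std::runtime_error("division by zero");
  HP dm = d; // mantissa only
  dm.sign = 1;
  long long de = d.e;
  dm.e = 0;
  HP r = fromDouble(1.0 / dm.toDouble());
  HP two = fromDouble(2.0);
  int bits = 50;
  while (bits < 32 * NL + 32) {
    r = r * (two - dm * r);
    bits *= 2;
  }
  r.e -= de;
  if (d.sign < 0) r.sign = -r.sign;
  return r;
}

HP HP::sqrt(const HP &x) {
  if (x.sign < 0) throw std::runtime_error("sqrt of negative");
  if (x.sign == 0) return HP();
  long long k = (x.e >= 0) ? x.e / 2 : -(((-x.e) + 1) / 2);
  HP mm = x; // x * B^(-2k), in [1, B^2)
  mm.e = x.e - 2 * k;
  // Newton on y = 1/sqrt(mm)
  HP y = fromDouble(1.0 / std::sqrt(mm.toDouble()));
  HP half = fromDouble(0.5), three = fromDouble(3.0);
  int bits = 50;
  while (bits < 32 * NL + 32) {
    y = y * (three - mm * y * y) * half;
    bits *= 2;
  }
  HP r = mm * y;
  r.e += k;
  return r;
}

static std::map<int, HP> ln2_cache, pi_cache;

const HP &HP::ln2() {
  auto it = ln2_cache.find(NL);
  if (it != ln2_cache.end()) return it->second;
  // ln 2 = 2 atanh(1/3) = 2 sum_k (1/3)^(2k+1) / (2k+1)
  HP t = fromDouble(1.0).divSmall(3); // (1/3)^(2k+1)
  HP s;
  int kmax = (int)(32 * NL / std::log2(9.0)) + 8;
  for (int k = 0; k <= kmax; k++) {
    s += t.divSmall(2 * k + 1);
    t = t.divSmall(9);
  }
  ln2_cache[NL] = s.mulSmall(2);
  return ln2_cache[NL];
}

static HP atanInvInt(uint32_t a) { // atan(1/a), a >= 2
  HP t = HP::fromDouble(1.0).divSmall(a);
  uint64_t a2 = (uint64_t)a * a;
  HP s;
  int kmax = (int)(32 * HP::NL / std::log2((double)a2)) + 8;
  for (int k = 0; k <= kmax; k++) {
    HP term = t.divSmall(2 * k + 1);
    if (k % 2) s -= term; else s += term;
    if (a2 >> 32) {
      t = t.divSmall(a).divSmall(a);
    } else {
      t = t.divSmall((uint32_t)a2);
    }
  }
  return s;
}

const HP &HP::pi() {
  auto it = pi_cache.find(NL);
  if (it != pi_cache.end()) return it->second;
  // Machin: pi = 16 atan(1/5) - 4 atan(1/239)
  HP p = atanInvInt(5).mulSmall(16) - atanInvInt(239).mulSmall(4);
  pi_cache[NL] = p;
  return pi_cache[NL];
}

HP HP::exp(const HP &x) {
  if (x.sign == 0) return fromDouble(1.0);
  double xd = x.toDouble();
  if (xd < -0.35 * 32 * NL * 22.18) return HP(); // deep underflow -> 0
  if (xd > 1e15 || xd < -1e15) throw std::runtime_error("exp overflow");
  long long n = (long long)std::llround(xd / 0.6931471805599453);
  HP y = x - ln2().mulSmall((uint32_t)std::llabs(n)) * fromDouble(n >= 0 ? 1.0 : -1.0);
  // |y| <= ~0.35; scale down by 2^6
  const int S = 6;
  y.e -= 0; // scaling via divSmall(64)
  y = y.divSmall(64);
  HP s = fromDouble(1.0), t = fromDouble(1.0);
  int kmax = 8 + (int)(32 * NL * 0.693 / 5.0);
  for (int k = 1; k <= kmax; k++) {
    t = (t * y).divSmall((uint32_t)k);
    s += t;
    if (t.sign == 0) break;
  }
  for (int i = 0; i < S; i++) s = s * s;
  return s * pow2(n);
}

HP HP::ln(const HP &x) {
  if (x.sign <= 0) throw std::runtime_error("ln of non-positive");
  // x = M * B^e with M in [1, B): ln x = ln M + 32 e ln 2;
  // reduce M to [0.75, 1.5) by pulling out powers of two, then
  // ln m = 2 atanh((m-1)/(m+1))
  HP m = x;
  long long e32 = 32 * x.e;
  m.e = 0;
  double md = m.toDouble();
  int k2 = (int)std::lround(std::log2(md));
  m = m * pow2(-k2);
  long long n2 = e32 + k2;
  HP u = (m - HP(1.0)) / (m + HP(1.0));
  HP u2 = u * u, t = u, s;
  int kmax = 8 + (int)(32 * NL / std::max(4.0, -std::log2(u2.toDouble() + 1e-30)));
  for (int k = 0; k <= kmax; k++) {
    s += t.divSmall(2 * k + 1);
    t = t * u2;
    if (t.isZero()) break;
  }
  HP r = s.mulSmall(2);
  HP nl = ln2().mulSmall((uint32_t)std::llabs(n2));
  if (n2 >= 0) r += nl; else r -= nl;
  return r;
}
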