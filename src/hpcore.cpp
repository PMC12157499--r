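// Protein-side pipeline in high-precision arithmetic.  The birth-state
// generating function has an order-a branch point at finite distance, so
// the coefficient recursion and the series inversion both involve
// cancellations far beyond double or quadruple range at physiological a;
// all sums here run in the HP big-float type (~150 decimal digits by
// default).

#include "hpcore.h"
#include <algorithm>
#include <cmath>
#include <cstdio>

bool g_inv_debug = false;

HP hp_from_quad(quad x) {
  double hi = (double)x;
  quad r1 = x - (quad)hi;
  double mid = (double)r1;
  double lo = (double)(r1 - (quad)mid);
  return HP(hi) + HP(mid) + HP(lo);
}

std::vector<HP> hp_laplace_grid(const DivModel &m, double gp, int K) {
  std::vector<HP> L(K + 1);
  HP gph = HP(gp);
  switch (m.family) {
  case 1: { // delta: exp(-s gp T), via running product of exp(-gp T)
    HP x = HP(-m.p1) * gph;
    HP ex = HP::exp(x), run = HP(1.0);
    for (int s = 0; s <= K; s++) {
      L[s] = run;
      run = run * ex;
    }
    break;
  }
  case 2: { // exponential, mean T: 1/(1 + s gp T)
    HP T = HP(m.p1);
    for (int s = 0; s <= K; s++)
      L[s] = HP::recip(HP(1.0) + gph.mulSmall((uint32_t)s) * T);
    break;
  }
  case 3: { // erlang: (lam/(lam+s gp))^N
    HP lam = HP(m.p2);
    int N = (int)m.p1;
    for (int s = 0; s <= K; s++) {
      HP base = lam * HP::recip(lam + gph.mulSmall((uint32_t)s));
      HP p = HP(1.0);
      for (int i = 0; i < N; i++) p = p * base;
      L[s] = p;
    }
    break;
  }
  case 4: { // beta-exponential: prod_i beta*i/(beta*i + s gp)
    HP beta = HP(m.p3);
    int X = (int)m.p1, n0 = (int)m.p2;
    for (int s = 0; s <= K; s++) {
      HP sg = gph.mulSmall((uint32_t)s);
      HP p = HP(1.0);
      for (int i = n0; i <= X - 1; i++) {
        HP bi = beta.mulSmall((uint32_t)i);
        p = p * bi * HP::recip(bi + sg);
      }
      L[s] = p;
    }
    break;
  }
  default: { // quadrature families: quad accuracy inputs
    for (int s = 0; s <= K; s++)
      L[s] = hp_from_quad(m.laplace(quad(s) * quad(gp)));
  }
  }
  return L;
}

// binomial coefficient C(a, l) for real a, as a running product
static std::vector<HP> binom_a_table(double a, int K) {
  std::vector<HP> C(K + 1);
  C[0] = HP(1.0);
  bool a_int = std::fabs(a - std::round(a)) < 1e-12;
  for (int l = 1; l <= K; l++) {
    if (a_int && l > (int)std::round(a)) {
      C[l] = HP(); // zero
    } else {
      C[l] = C[l - 1] * HP(a - (l - 1)) / HP((double)l);
    }
  }
  return C;
}

// Collapsed form of the exact protein recursion: with c_j = F_j / j!,
//   D_s = sum_{l=0}^{s} C(a,l) (-b)^l c_{s-l}
//   F_k (1 - 2^-k L_k) = a k! 2^-k [ sum_{s<k} L_s b^{k-s} A_{k-s} D_s/(k-s)!
//                                    + L_k (D_k - c_k)/a ]
// where A_m = Gamma(a+m)/Gamma(a+1).  This is an exact refactoring of the
// printed double sum over (l, j) with s = l + j.
std::vector<HP> protein_coeffs_hp(const DivModel &m, double a, double b,
                                  double gp, int K) {
  std::vector<HP> L = hp_laplace_grid(m, gp, K);
  std::vector<HP> Ca = binom_a_table(a, K);
  std::vector<HP> A(K + 1), invfact(K + 1), powmb(K + 1), powb(K + 1);
  A[0] = HP::recip(HP(a)); // Gamma(a)/Gamma(a+1)
  for (int mm = 1; mm <= K; mm++) A[mm] = A[mm - 1] * HP(a + mm - 1);
  invfact[0] = HP(1.0);
  for (int i = 1; i <= K; i++) invfact[i] = invfact[i - 1] / HP((double)i);
  powmb[0] = powb[0] = HP(1.0);
  for (int i = 1; i <= K; i++) {
    powmb[i] = powmb[i - 1] * HP(-b);
    powb[i] = powb[i - 1] * HP(b);
  }
  HP ah = HP(a);
  std::vector<HP> F(K + 1), c(K + 1), D(K + 1);
  F[0] = c[0] = HP(1.0);
  D[0] = HP(1.0);
  for (int k = 1; k <= K; k++) {
    // S = sum_{s<k} L_s b^(k-s) A_(k-s) D_s / (k-s)!  +  L_k (D_k^-)/a
    // where D_k^- = D_k - c_k = sum_{l>=1} C(a,l)(-b)^l c_{k-l}
    HP Dkm;
    for (int l = 1; l <= k; l++) {
      if (Ca[l].isZero()) continue;
      Dkm += Ca[l] * powmb[l] * c[k - l];
    }
    HP S;
    for (int s = 0; s < k; s++)
      S += L[s] * powb[k - s] * A[k - s] * invfact[k - s] * D[s];
    S += L[k] * Dkm * A[0]; // the j<k part of the s=k term
    // prefactor a k! 2^-k; solve the linear step for F_k
    HP rhs = ah * S * HP::pow2(-k); // times k! applied at the end
    HP denom = HP(1.0) - L[k] * HP::pow2(-k);
    HP ck = rhs / denom; // this is F_k 2^... careful: rhs currently = F_k/k! * denom
    // rhs = a 2^-k S = (F_k / k!) * denom  =>  c_k = rhs/denom
    c[k] = ck;
    F[k] = ck / invfact[k];
    D[k] = Dkm + c[k];
  }
  return F;
}

std::vector<HP> protein_age_coeffs_hp(const std::vector<HP> &F, double a,
                                      double b, double gp, double tau) {
  int K = (int)F.size() - 1;
  std::vector<HP> Ca = binom_a_table(a, K);
  std::vector<HP> A(K + 1), invfact(K + 1), fact(K + 1), powmb(K + 1),
      powb(K + 1), powE(K + 1);
  A[0] = HP::recip(HP(a));
  for (int mm = 1; mm <= K; mm++) A[mm] = A[mm - 1] * HP(a + mm - 1);
  invfact[0] = fact[0] = HP(1.0);
  for (int i = 1; i <= K; i++) {
    fact[i] = fact[i - 1] * HP((double)i);
    invfact[i] = invfact[i - 1] / HP((double)i);
  }
  powmb[0] = powb[0] = powE[0] = HP(1.0);
  HP E = HP::exp(HP(-gp * tau));
  for (int i = 1; i <= K; i++) {
    powmb[i] = powmb[i - 1] * HP(-b);
    powb[i] = powb[i - 1] * HP(b);
    powE[i] = powE[i - 1] * E;
  }
  // c_j = F_j/j!; D_s = sum_l C(a,l)(-b)^l c_(s-l);
  // G_k = a k! sum_{s<=k} E^s b^(k-s) A_(k-s) D_s / (k-s)!
  std::vector<HP> c(K + 1), D(K + 1), G(K + 1);
  for (int j = 0; j <= K; j++) c[j] = F[j] * invfact[j];
  HP ah = HP(a);
  for (int s = 0; s <= K; s++) {
    HP d;
    for (int l = 0; l <= s; l++) {
      if (Ca[l].isZero()) continue;
      d += Ca[l] * powmb[l] * c[s - l];
    }
    D[s] = d;
  }
  G[0] = HP(1.0);
  for (int k = 1; k <= K; k++) {
    HP S;
    for (int s = 0; s <= k; s++)
      S += powE[s] * powb[k - s] * A[k - s] * invfact[k - s] * D[s];
    G[k] = ah * fact[k] * S;
  }
  return G;
}

// ---------------------------------------------------------------- inversion

// One Taylor shift by -h of the scaled coefficient vector (c_j are the
// current local Taylor coefficients); the returned table is truncated to
// the orders whose shift sums genuinely converged (geometric tail well
// below the max term) -- the truncation regularizes the continuation of
// boundary-divergent series.  lnz tracks per-order noise in log2.
struct ShiftOutHP {
  std::vector<HP> c;
  std::vector<double> lnz;
  int K_reliable;
};

static const double TAIL_BITS = 64.0; // tail must sit 2^-64 below the peak

// shared factorial tables, grown on demand
static std::vector<HP> g_fact(1, HP(1.0)), g_invfact(1, HP(1.0));
static void grow_fact(int K) {
  for (int i = (int)g_fact.size(); i <= K; i++) {
    g_fact.push_back(g_fact[i - 1] * HP((double)i));
    g_invfact.push_back(g_invfact[i - 1] / HP((double)i));
  }
}

// does the shift sum for order j have a resolved (deeply decayed) tail?
static bool reliable_at(const std::vector<HP> &c, double h, int j) {
  int K = (int)c.size() - 1;
  if (K - j < 12) return false;
  int ntail = std::max(4, (K - j) / 10);
  double mxl = -1e18, taill = -1e18;
  double lh = std::log2(h);
  // log-magnitude scan only (no HP ops): log2|term| =
  //   log2|c_k| + log2 C(k,j) + (k-j) log2 h
  for (int k = j; k <= K; k++) {
    if (c[k].isZero()) continue;
    double lb = (std::lgamma(k + 1.0) - std::lgamma(j + 1.0) -
                 std::lgamma(k - j + 1.0)) / M_LN2;
    double tl = c[k].log2abs() + lb + (k - j) * lh;
    if (tl > mxl) mxl = tl;
    if (K - k < ntail && tl > taill) taill = tl;
  }
  return taill + std::log2((double)std::max(4, (K - j) / 10)) <=
         mxl - TAIL_BITS;
}

// largest reliable order (>= need), by scan from need upward; -1 if none
static int estimate_Krel(const std::vector<HP> &c, double h, int need) {
  int K = (int)c.size() - 1;
  if (!reliable_at(c, h, need)) return -1;
  int j = need;
  int step = std::max(1, (K - need) / 16);
  while (j + step <= K - 12 && reliable_at(c, h, j + step)) j += step;
  return j;
}

static ShiftOutHP taylor_shift_hp(const std::vector<HP> &c,
                                  const std::vector<double> &lnz, double h) {
  int K = (int)c.size() - 1;
  grow_fact(K);
  ShiftOutHP out;
  out.c.resize(K + 1);
  out.lnz.assign(K + 1, -1e18);
  out.K_reliable = -1;
  const double eps_log2 = -32.0 * (HP::NL - 2);
  HP hh = HP(h);
  std::vector<HP> powh(K + 1);
  powh[0] = HP(1.0);
  for (int i = 1; i <= K; i++) powh[i] = powh[i - 1] * (-hh);
  bool still = true;
  for (int j = 0; j <= K; j++) {
    int ntail = std::max(4, (K - j) / 10);
    HP s, tail;
    double mxl = -1e18, nzl = -1e18;
    for (int k = j; k <= K; k++) {
      HP term = c[k] * g_fact[k] * g_invfact[j] * g_invfact[k - j] *
                powh[k - j];
      s += term;
      double tl = term.log2abs();
      if (tl > mxl) mxl = tl;
      if (K - k < ntail) tail += HP::abs(term);
      if (!c[k].isZero()) {
        double nz = lnz[k] + (tl - c[k].log2abs());
        if (nz > nzl) nzl = nz;
      }
    }
    out.c[j] = s;
    out.lnz[j] = std::max(nzl, mxl + eps_log2) + 6; // slack for accumulation
    bool reliable = (K - j >= 12) && (tail.log2abs() <= mxl - TAIL_BITS);
    if (!reliable) still = false;
    if (still) out.K_reliable = j;
  }
  return out;
}

InvResult invert_series_hp(const std::vector<HP> &C, double factor, int ymax) {
  int K = (int)C.size() - 1;
  grow_fact(K);
  InvResult res;
  res.p.assign(ymax + 1, 0.0);
  res.method.assign(ymax + 1, 1);
  res.noise.assign(ymax + 1, 0.0);
  res.converged = true;
  const double eps_log2 = -32.0 * (HP::NL - 2);
  // scaled local Taylor coefficients about q = 1: c_k = C_k factor^k / k!
  std::vector<HP> c(K + 1);
  {
    HP f = HP(1.0), fh = HP(factor);
    for (int k = 0; k <= K; k++) {
      if (k > 0) f = f * fh;
      c[k] = C[k] * f * g_invfact[k];
    }
  }
  // fast path: direct alternating sums with stabilization monitoring
  {
    bool all_ok = true;
    std::vector<double> pd(ymax + 1), nd(ymax + 1);
    for (int y = 0; y <= ymax && all_ok; y++) {
      HP S;
      double mxl = -1e18, lastl = -1e18;
      int win = std::max(10, K / 10);
      HP smax, smin;
      bool first = true;
      for (int k = y; k <= K; k++) {
        HP term = c[k] * g_fact[k] * g_invfact[y] * g_invfact[k - y];
        if ((k - y) % 2) term.sign = -term.sign;
        S += term;
        lastl = term.log2abs();
        if (lastl > mxl) mxl = lastl;
        if (K - k < win) {
          if (first) {
            smax = smin = S;
            first = false;
          } else {
            if (smax < S) smax = S;
            if (S < smin) smin = S;
          }
        }
      }
      double osc = (smax - smin).log2abs();
      double dn = mxl + eps_log2;
      if (osc < -43.0 && lastl < -47.0 && dn < -40.0) { // ~1e-13, 1e-14, 1e-12
        pd[y] = S.toDouble();
        nd[y] = std::pow(2.0, dn);
      } else {
        all_ok = false;
      }
    }
    if (all_ok) {
      res.p = pd;
      res.noise = nd;
      return res;
    }
  }
  // robust path: truncated Taylor-shift continuation from q = 1 to q = 0.
  // Step size is chosen for efficiency (progress per truncated order): big
  // shifts push the convergent range of the shifted sums far beyond the
  // available table and waste orders, tiny shifts spend the 12-order floor
  // repeatedly.
  std::vector<double> lnz(K + 1, -1e18);
  for (int k = 0; k <= K; k++)
    if (!c[k].isZero()) lnz[k] = c[k].log2abs() + eps_log2;
  double q = 1.0;
  int steps = 0;
  bool failed = false;
  while (q > 1e-12 && steps < 64) {
    int Kc = (int)c.size() - 1;
    // Candidate step sizes.  Consumption of table orders is multiplicative
    // (the reliable range shrinks by the hump factor of the shift), so the
    // figure of merit is log-shrinkage per unit of progress; candidates are
    // ranked by a cheap log-magnitude prediction, then the best few are
    // evaluated by the actual shift.
    const double fr[8] = {1.0, 0.75, 0.5, 0.375, 0.25, 0.1875, 0.125, 0.0625};
    double pred[8];
    int order[8];
    for (int d = 0; d < 8; d++) {
      double h = q * fr[d];
      bool fin = (d == 0);
      int need = fin ? ymax : std::min(Kc, ymax + 10);
      int kr = estimate_Krel(c, h, need);
      pred[d] = (kr < need)
                    ? 1e18
                    : (fin ? -1.0 : std::log((double)Kc / (double)kr) / h);
      order[d] = d;
    }
    std::sort(order, order + 8,
              [&](int i, int j) { return pred[i] < pred[j]; });
    double hsel = -1;
    bool fin_sel = false;
    ShiftOutHP best;
    double best_cost = 1e18;
    int evaluated = 0;
    for (int oi = 0; oi < 8 && evaluated < 3; oi++) {
      int d = order[oi];
      if (pred[d] >= 1e18) break;
      double h = q * fr[d];
      bool fin = (d == 0);
      int need = fin ? ymax : std::min(Kc, ymax + 10);
      ShiftOutHP so = taylor_shift_hp(c, lnz, h);
      evaluated++;
      if (so.K_reliable < need) continue;
      double cost =
          fin ? -1.0 : std::log((double)Kc / (double)so.K_reliable) / h;
      if (cost < best_cost) {
        best_cost = cost;
        best = std::move(so);
        hsel = h;
        fin_sel = fin;
      }
      if (fin_sel) break;
    }
    bool advanced = false;
    if (hsel > 0) {
      best.c.resize(best.K_reliable + 1);
      best.lnz.resize(best.K_reliable + 1);
      c.swap(best.c);
      lnz.swap(best.lnz);
      q -= hsel;
      advanced = true;
    }
    if (g_inv_debug)
      std::printf("  [inv] q=%.4f K=%d -> h=%.4f adv=%d K'=%d\n", q + (advanced ? hsel : 0),
                  Kc, hsel, advanced, (int)c.size() - 1);
    if (!advanced) {
      failed = true;
      break;
    }
    steps++;
    if (fin_sel && q <= 1e-12) break;
  }
  if (failed || q > 1e-12) res.converged = false;
  for (int y = 0; y <= ymax; y++) {
    res.p[y] = (y < (int)c.size()) ? c[y].toDouble() : 0.0;
    res.method[y] = 2;
    res.noise[y] =
        (y < (int)lnz.size()) ? std::pow(2.0, std::min(lnz[y], 100.0)) : 0.0;
    if (res.noise[y] > 1e-8) res.converged = false;
  }
  return res;
}

// ------------------------------------------- level-2 peeled representation

// Taylor coefficients of R2(z) = (1-bz)^a (1-bz/2)^-a (1-bz/4)^-a by the
// stable forward recurrence from R2' * (1-bz)(1-bz/2)(1-bz/4) =
// a b R2 * (-1/4 - bz/4 + (bz)^2/8) (log-derivative identity).
static std::vector<HP> r2_kernel(double a, double b, int K) {
  std::vector<HP> r(K + 1);
  r[0] = HP(1.0);
  HP bh(b), ab(a * b);
  for (int m = 0; m <= K - 1; m++) {
    HP s;
    s += bh * r[m] * HP(7.0 * m / 4.0);
    if (m >= 1) s -= bh * bh * r[m - 1] * HP(7.0 * (m - 1) / 8.0);
    if (m >= 2) s += bh * bh * bh * r[m - 2] * HP((m - 2) / 8.0);
    s -= ab * r[m] * HP(0.25);
    if (m >= 1) s -= ab * bh * r[m - 1] * HP(0.25);
    if (m >= 2) s += ab * bh * bh * r[m - 2] * HP(0.125);
    r[m + 1] = s.divSmall((uint32_t)(m + 1));
  }
  return r;
}

// binomial series coefficients of (1 + c - c q)^(-a): positive, geometric
static std::vector<HP> nbneg_series(double c, double a, int n) {
  std::vector<HP> u(n + 1);
  HP onec = HP(1.0) + HP(c);
  HP sig = HP(c) / onec;
  u[0] = HP::exp(HP(-a) * HP::ln(onec));
  for (int i = 0; i < n; i++)
    u[i + 1] = u[i] * sig * HP(a + i).divSmall((uint32_t)(i + 1));
  return u;
}

// coefficients of (1 + c - c q)^(+a): alternating, terminating for integer a
static std::vector<HP> pospow_series(double c, double a, int n) {
  std::vector<HP> v(n + 1);
  HP onec = HP(1.0) + HP(c);
  HP sig = HP(c) / onec;
  v[0] = HP::exp(HP(a) * HP::ln(onec));
  bool a_int = std::fabs(a - std::round(a)) < 1e-12;
  for (int i = 0; i < n; i++) {
    if (a_int && i >= (int)std::round(a)) {
      v[i + 1] = HP();
      continue;
    }
    v[i + 1] = v[i] * (-sig) * HP(a - i).divSmall((uint32_t)(i + 1));
  }
  return v;
}

// coefficients of Psi2(1+x) about x = 0 from the functional equation
//   Psi2(1+x) = (1 - bx/4)^a sum_m w_m (x/2)^m L_m,
//   w_m = sum_j r2_(m-j) psi2_j,
// solving the linear step for psi2_k (the unknown appears once, through
// w_k with weight 2^-k L_k).
std::vector<HP> psi2_coeffs_hp(const DivModel &m, double a, double b,
                               double gp, int K) {
  std::vector<HP> L = hp_laplace_grid(m, gp, K);
  std::vector<HP> r2 = r2_kernel(a, b, K);
  // alpha_i = C(a,i) (-b/4)^i
  std::vector<HP> alpha(K + 1);
  alpha[0] = HP(1.0);
  HP mb4 = HP(-b / 4.0);
  bool a_int = std::fabs(a - std::round(a)) < 1e-12;
  for (int i = 1; i <= K; i++) {
    if (a_int && i > (int)std::round(a)) {
      alpha[i] = HP();
    } else {
      alpha[i] = alpha[i - 1] * HP(a - (i - 1)) * mb4;
      alpha[i] = alpha[i].divSmall((uint32_t)i);
    }
  }
  std::vector<HP> beta(K + 1); // 2^-m L_m
  for (int mm = 0; mm <= K; mm++) beta[mm] = L[mm] * HP::pow2(-mm);
  std::vector<HP> psi2(K + 1), w(K + 1);
  psi2[0] = HP(1.0);
  w[0] = HP(1.0);
  for (int k = 1; k <= K; k++) {
    HP wkm; // partial w_k without the psi2_k term
    for (int j = 0; j < k; j++) wkm += r2[k - j] * psi2[j];
    HP S = beta[k] * wkm;
    for (int mm = 0; mm < k; mm++) {
      if (alpha[k - mm].isZero()) continue;
      S += alpha[k - mm] * beta[mm] * w[mm];
    }
    psi2[k] = S / (HP(1.0) - beta[k]);
    w[k] = wkm + psi2[k];
  }
  return psi2;
}

// Phi_y = sum_k psi2_k s^k C(k,y) (-1)^(k-y): the Taylor coefficients of
// Psi2(1 + s(q-1)) about q = 0.  The terms rise to a binomial hump near
// k ~ y/(1 - s/R) (R ~ 3 is the empirical analyticity radius of Psi2) and
// then decay geometrically; the sum runs over the whole table and the last
// window of terms is reported as the truncation noise, so an insufficient
// table is detected by the caller's convergence check.
static std::vector<HP> phi_series(const std::vector<HP> &psi2, double s,
                                  int ymax, std::vector<double> &noise) {
  int K = (int)psi2.size() - 1;
  grow_fact(K);
  std::vector<HP> t(K + 1);
  {
    HP sp = HP(1.0), sh = HP(s);
    for (int k = 0; k <= K; k++) {
      t[k] = psi2[k] * sp;
      sp = sp * sh;
    }
  }
  std::vector<HP> phi(ymax + 1);
  noise.assign(ymax + 1, 0.0);
  const double eps_log2 = -32.0 * (HP::NL - 2);
  for (int y = 0; y <= ymax; y++) {
    HP S;
    double mxl = -1e18, taill = -1e18;
    int win = std::max(8, (K - y) / 12);
    for (int k = y; k <= K; k++) {
      HP term = t[k] * g_fact[k] * g_invfact[y] * g_invfact[k - y];
      if ((k - y) % 2) term.sign = -term.sign;
      S += term;
      double tl = term.log2abs();
      if (tl > mxl) mxl = tl;
      if (K - k < win && tl > taill) taill = tl;
    }
    double nz = std::max(taill + std::log2((double)win), mxl + eps_log2);
    noise[y] = std::pow(2.0, std::min(nz, 100.0));
    phi[y] = S;
  }
  return phi;
}

static std::vector<HP> conv_hp(const std::vector<HP> &u,
                               const std::vector<HP> &v, int n) {
  std::vector<HP> out(n + 1);
  for (int i = 0; i <= n; i++) {
    HP s;
    for (int j = 0; j <= i; j++) {
      if (j >= (int)u.size() || i - j >= (int)v.size()) continue;
      if (u[j].isZero() || v[i - j].isZero()) continue;
      s += u[j] * v[i - j];
    }
    out[i] = s;
  }
  return out;
}

static InvResult assemble_protein_pmf(const std::vector<HP> &psi2, double a,
                                       double b, double gp, int state,
                                       double tau, int ymax) {
  double s = (state == 2) ? 2.0 : (state == 3 ? std::exp(-gp * tau) : 1.0);
  std::vector<double> phinoise;
  std::vector<HP> acc = phi_series(psi2, s, ymax, phinoise);
  std::vector<std::vector<HP>> factors;
  if (state == 1) {
    factors.push_back(nbneg_series(b / 2.0, a, ymax));
    factors.push_back(nbneg_series(b / 4.0, a, ymax));
  } else if (state == 2) {
    factors.push_back(nbneg_series(b, a, ymax));
    factors.push_back(nbneg_series(b / 2.0, a, ymax));
  } else {
    double E = std::exp(-gp * tau);
    factors.push_back(nbneg_series(b, a, ymax));
    factors.push_back(pospow_series(b * E, a, ymax));
    factors.push_back(nbneg_series(b * E / 2.0, a, ymax));
    factors.push_back(nbneg_series(b * E / 4.0, a, ymax));
  }
  for (const auto &f : factors) acc = conv_hp(acc, f, ymax);
  InvResult res;
  res.p.resize(ymax + 1);
  res.method.assign(ymax + 1, 3);
  res.noise.resize(ymax + 1);
  res.converged = true;
  for (int y = 0; y <= ymax; y++) {
    res.p[y] = acc[y].toDouble();
    // truncation noise of Phi spreads through the explicit kernels, whose
    // total mass at q = 1 is bounded by ~1
    double nz = 0;
    for (int j = 0; j <= y; j++) nz += phinoise[j];
    res.noise[y] = nz;
    if (nz > 1e-7) res.converged = false;
  }
  return res;
}

// psi2 table length: birth/age evaluate Psi2 at distance <= 1 (hump near
// 1.5 y); the pre-division state is assembled as the g(ts)-average of
// age-ts PMFs, so it needs no deeper table
int protein_K_needed(int state, int ymax, int K_req) {
  (void)state;
  return std::max(4 * ymax + 150, K_req);
}

InvResult protein_pmf_hp(const DivModel &m, double a, double b, double gp,
                         int state, double tau, int ymax, int K) {
  if (state == 3 && gp * tau < 1e-14) state = 1;
  int Ke = protein_K_needed(state, ymax, K);
  std::vector<HP> psi2 = psi2_coeffs_hp(m, a, b, gp, Ke);
  if (state != 2) return assemble_protein_pmf(psi2, a, b, gp, state, tau, ymax);
  // pre-division: P-(y) = integral g(ts) P(y, age = ts) dts (the cell is
  // caught at age ts just before partitioning)
  if (m.family == 1)
    return assemble_protein_pmf(psi2, a, b, gp, 3, m.p1, ymax);
  Nodes nd = m.nodes_coarse();
  InvResult acc;
  acc.p.assign(ymax + 1, 0.0);
  acc.noise.assign(ymax + 1, 0.0);
  acc.method.assign(ymax + 1, 3);
  acc.converged = true;
  double wsum = 0;
  for (size_t i = 0; i < nd.t.size(); i++) {
    double g = (m.family == 7) ? m.tab_g[i] : (double)m.density(nd.t[i]);
    double w = (double)nd.w[i] * g;
    if (w <= 1e-16) continue;
    wsum += w;
    InvResult r =
        assemble_protein_pmf(psi2, a, b, gp, 3, (double)nd.t[i], ymax);
    for (int y = 0; y <= ymax; y++) {
      acc.p[y] += w * r.p[y];
      acc.noise[y] += w * r.noise[y];
    }
    if (!r.converged) acc.converged = false;
  }
  // wsum ~ 1 up to the quadrature truncation; report through the total mass
  return acc;
}

std::vector<HP> hp_psi2_for(const DivModel &m, double a, double b, double gp,
                            int K) {
  return psi2_coeffs_hp(m, a, b, gp, K);
}
InvResult assemble_protein_pmf_psi2(const std::vector<HP> &psi2, double a,
                                    double b, double gp, int state, double tau,
                                    int ymax) {
  if (state == 3 && gp * tau < 1e-14) state = 1;
  return assemble_protein_pmf(psi2, a, b, gp, state, tau, ymax);
}
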