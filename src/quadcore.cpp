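// Quadruple-precision numerical core: division-time quadratures, the
// generating-function coefficient recursions, and series inversion of the
// coefficient tables into probability mass functions.
//
// The alternating series inverting the coefficients lose roughly
// exp(2 * mean) of relative precision to cancellation, and the protein
// series can be outright divergent (radius of convergence of the birth
// generating function about q = 1 can be <= 1 for geometric bursts), so the
// whole pipeline runs in __float128 (~33 significant digits) with Borel
// summation as the fallback for non-stabilizing sums.

#include "quadcore.h"
#include <map>
#include <cmath>

static const quad QEPS = 2e-34;

// ---------------------------------------------------------------- GL rule

const QuadGL &gl_rule(int n) {
  static std::map<int, QuadGL> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  QuadGL r;
  r.x.resize(n);
  r.w.resize(n);
  for (int i = 0; i < n; i++) {
    // Chebyshev initial guess, then Newton in quad precision
    quad x = cosq(M_PIq * (quad(i) + quad(0.75)) / (quad(n) + quad(0.5)));
    quad dp = 0;
    for (int iter = 0; iter < 6; iter++) {
      quad p0 = 1, p1 = x;
      for (int k = 2; k <= n; k++) {
        quad pk = ((2 * k - 1) * x * p1 - (k - 1) * p0) / k;
        p0 = p1;
        p1 = pk;
      }
      dp = n * (x * p1 - p0) / (x * x - 1);
      quad dx = p1 / dp;
      x -= dx;
      if (fabsq(dx) < 1e-33Q * (fabsq(x) + 1e-30Q)) {
        // one more refinement pass for the weight's derivative
      }
    }
    r.x[n - 1 - i] = x;
    r.w[n - 1 - i] = 2 / ((1 - x * x) * dp * dp);
  }
  cache[n] = r;
  return cache[n];
}

static void add_panel(Nodes &nd, quad a, quad b, int n) {
  const QuadGL &gl = gl_rule(n);
  quad h = (b - a) / 2, c = (b + a) / 2;
  for (int i = 0; i < n; i++) {
    nd.t.push_back(c + h * gl.x[i]);
    nd.w.push_back(h * gl.w[i]);
  }
}

// --------------------------------------------------------------- densities

quad DivModel::density(quad t) const {
  switch (family) {
  case 2: { // exponential, mean p1
    quad T = p1;
    return expq(-t / T) / T;
  }
  case 3: { // erlang, shape p1, rate p2
    quad N = p1, lam = p2;
    return expq(N * logq(lam) + (N - 1) * logq(t) - lam * t - lgammaq(N));
  }
  case 4: { // beta-exponential: threshold p1 = X, initial p2 = n0, rate p3
    quad X = p1, n0 = p2, beta = p3;
    quad lB = lgammaq(n0) + lgammaq(X - n0) - lgammaq(X);
    quad one_m = -expm1q(-beta * t); // 1 - exp(-beta t)
    return expq(logq(beta) - beta * n0 * t + (X - 1 - n0) * logq(one_m) - lB);
  }
  case 5: { // growth-rate heterogeneity: p1 = beta0, p2 = sigma_beta
    quad b0 = p1, sb = p2, l2 = logq(quad(2));
    quad z = (b0 * t - l2);
    return expq(logq(l2) - 2 * logq(t) -
                quad(0.5) * logq(2 * M_PIq * sb * sb) -
                z * z / (2 * t * t * sb * sb));
  }
  case 6: { // fluctuating threshold: p1 = beta0, p2 = sigma_beta, p3 = sigma_X
    quad b0 = p1, sb = p2, sx = p3, l2 = logq(quad(2));
    quad v = sx * sx + sb * sb * t * t;
    quad z = (b0 * t - l2);
    return (b0 * sx * sx + sb * sb * t * l2) /
           (sqrtq(2 * M_PIq) * powq(v, quad(1.5))) * expq(-z * z / (2 * v));
  }
  default:
    throw std::runtime_error("density: unsupported family");
  }
}

// ------------------------------------------------------------------- nodes

static Nodes build_nodes(const DivModel &mod, int NN, int fine_panels,
                         double wu);

Nodes DivModel::nodes() const { return build_nodes(*this, 32, 24, 35.0); }
// lighter rule for smooth t-averages: narrower panels, fewer nodes each
Nodes DivModel::nodes_coarse() const { return build_nodes(*this, 12, 16, 18.0); }

static Nodes build_nodes(const DivModel &mod, int NN, int fine_panels,
                         double wu) {
  Nodes nd;
  switch (mod.family) {
  case 2: { // decay rate 1/T; keep rate*width <= ~35 per panel
    quad T = mod.p1, U = 140 * T, w = wu * T;
    for (quad a = 0; a < U; a += w) add_panel(nd, a, a + w, NN);
    break;
  }
  case 3: {
    quad N = mod.p1, lam = mod.p2;
    quad U = (N + 40 * sqrtq(N) + 140) / lam, w = wu / lam;
    for (quad a = 0; a < U; a += w) add_panel(nd, a, a + w, NN);
    break;
  }
  case 4: {
    quad minrate = mod.p3 * mod.p2; // beta * n0 is the slowest stage
    quad U = 140 / minrate, w = wu / minrate;
    for (quad a = 0; a < U; a += w) add_panel(nd, a, a + w, NN);
    break;
  }
  case 5:
  case 6: {
    quad b0 = mod.p1, sb = mod.p2, sx = (mod.family == 6) ? quad(mod.p3) : quad(0);
    quad l2 = logq(quad(2));
    quad m0 = l2 / b0;
    quad bhi = b0 + 13 * sb;
    quad blo = b0 - 13 * sb;
    if (blo < b0 / 50) blo = b0 / 50;
    quad lo = (l2 - 13 * sx > 0 ? l2 - 13 * sx : l2 / 100) / bhi;
    quad hi = (l2 + 13 * sx) / blo;
    // fine panels over the bulk
    int np = fine_panels;
    quad w = (hi - lo) / np;
    add_panel(nd, lo / 5, lo, NN);
    for (int i = 0; i < np; i++) add_panel(nd, lo + i * w, lo + (i + 1) * w, NN);
    // geometric panels over the slowly decaying tail
    quad U = 60 * m0;
    for (quad a = hi; a < U; a = 2 * a) add_panel(nd, a, (2 * a < U ? 2 * a : U), NN);
    break;
  }
  case 7: {
    nd.t.resize(mod.tab_t.size());
    nd.w.resize(mod.tab_t.size());
    for (size_t i = 0; i < mod.tab_t.size(); i++) {
      nd.t[i] = mod.tab_t[i];
      nd.w[i] = mod.tab_w[i];
    }
    break;
  }
  default:
    throw std::runtime_error("nodes: unsupported family");
  }
  return nd;
}

static quad node_density(const DivModel &m, size_t i, const Nodes &nd) {
  if (m.family == 7) return m.tab_g[i];
  return m.density(nd.t[i]);
}

// ----------------------------------------------------------------- Laplace

quad DivModel::laplace(quad s) const {
  switch (family) {
  case 1:
    return expq(-s * quad(p1));
  case 2:
    return 1 / (1 + s * quad(p1));
  case 3:
    return powq(quad(p2) / (quad(p2) + s), quad(p1));
  case 4: {
    int X = (int)p1, n0 = (int)p2;
    quad beta = p3, L = 1;
    for (int i = n0; i <= X - 1; i++) L *= (beta * i) / (beta * i + s);
    return L;
  }
  default: { // 5, 6, 7: quadrature
    Nodes nd = nodes();
    quad L = 0;
    for (size_t i = 0; i < nd.t.size(); i++)
      L += nd.w[i] * node_density(*this, i, nd) * expq(-s * nd.t[i]);
    return L;
  }
  }
}

// ------------------------------------------------------------------- Psi


// Nodes for the Psi integrals: the factor (1 - e^{-gamma t})^m rises on the
// scale ln(m)/gamma and behaves like (gamma t)^m below it, so small t needs
// logarithmically spaced panels; the exponential tail of g is covered by
// linear panels a few decay lengths wide.
static Nodes psi_nodes(const DivModel &mod) {
  double scale, U;
  switch (mod.family) {
  case 2:
    scale = mod.p1;
    U = 140 * scale;
    break;
  case 3:
    scale = 1.0 / mod.p2;
    U = (mod.p1 + 40 * std::sqrt(mod.p1) + 140) / mod.p2;
    break;
  case 4:
    scale = 1.0 / (mod.p3 * mod.p2);
    U = 140 * scale;
    break;
  default:
    return mod.nodes();
  }
  Nodes nd;
  const int NN = 24;
  double lo = scale * 1e-7, hi = 4 * scale;
  int nlog = 44;
  double rat = std::pow(hi / lo, 1.0 / nlog);
  double a = lo;
  add_panel(nd, 0, quad(lo), NN);
  for (int i = 0; i < nlog; i++) {
    add_panel(nd, quad(a), quad(a * rat), NN);
    a *= rat;
  }
  double w = 6 * scale;
  for (double x = hi; x < U; x += w)
    add_panel(nd, quad(x), quad(std::min(x + w, U)), NN);
  return nd;
}

std::vector<std::vector<quad>> psi_matrix(const DivModel &m, quad gamma, int K) {
  std::vector<std::vector<quad>> P(K + 1, std::vector<quad>(K + 1, quad(0)));
  if (m.family == 1) {
    quad T = m.p1, E = expq(-gamma * T), M = -expm1q(-gamma * T);
    std::vector<quad> pe(K + 1), pm(K + 1);
    pe[0] = pm[0] = 1;
    for (int i = 1; i <= K; i++) {
      pe[i] = pe[i - 1] * E;
      pm[i] = pm[i - 1] * M;
    }
    for (int k = 0; k <= K; k++)
      for (int j = 0; j <= k; j++) P[k][j] = pe[j] * pm[k - j];
    return P;
  }
  Nodes nd = psi_nodes(m);
  std::vector<quad> pe(K + 1), pm(K + 1);
  for (size_t i = 0; i < nd.t.size(); i++) {
    quad g = nd.w[i] * node_density(m, i, nd);
    if (g == 0) continue;
    quad E = expq(-gamma * nd.t[i]), M = -expm1q(-gamma * nd.t[i]);
    pe[0] = pm[0] = 1;
    for (int q = 1; q <= K; q++) {
      pe[q] = pe[q - 1] * E;
      pm[q] = pm[q - 1] * M;
    }
    for (int k = 0; k <= K; k++) {
      std::vector<quad> &Pk = P[k];
      for (int j = 0; j <= k; j++) Pk[j] += g * pe[j] * pm[k - j];
    }
  }
  return P;
}

// ------------------------------------------------------------- recursions

std::vector<quad> mrna_coeffs(const DivModel &m, double km, double gm, int K) {
  std::vector<std::vector<quad>> Psi = psi_matrix(m, quad(gm), K);
  std::vector<quad> fact(K + 1), invfact(K + 1), pc(K + 1), half(K + 1);
  fact[0] = invfact[0] = pc[0] = half[0] = 1;
  quad c = quad(km) / quad(gm);
  for (int i = 1; i <= K; i++) {
    fact[i] = fact[i - 1] * i;
    invfact[i] = 1 / fact[i];
    pc[i] = pc[i - 1] * c;
    half[i] = half[i - 1] / 2;
  }
  std::vector<quad> F(K + 1);
  F[0] = 1;
  for (int k = 1; k <= K; k++) {
    quad S = 0;
    for (int j = 0; j < k; j++)
      S += fact[k] * invfact[j] * invfact[k - j] * pc[k - j] * Psi[k][j] * F[j];
    F[k] = S * half[k] / (1 - Psi[k][k] * half[k]);
  }
  return F;
}

// ------------------------------------------------------------- age tables

std::vector<quad> mrna_age_coeffs(const std::vector<quad> &F, double km,
                                  double gm, double tau) {
  int K = (int)F.size() - 1;
  quad E = expq(-quad(gm) * quad(tau)), M = -expm1q(-quad(gm) * quad(tau));
  quad c = quad(km) / quad(gm);
  std::vector<quad> fact(K + 1), invfact(K + 1), pc(K + 1), pe(K + 1), pm(K + 1);
  fact[0] = invfact[0] = pc[0] = pe[0] = pm[0] = 1;
  for (int i = 1; i <= K; i++) {
    fact[i] = fact[i - 1] * i;
    invfact[i] = 1 / fact[i];
    pc[i] = pc[i - 1] * c;
    pe[i] = pe[i - 1] * E;
    pm[i] = pm[i - 1] * M;
  }
  std::vector<quad> G(K + 1);
  for (int k = 0; k <= K; k++) {
    quad S = 0;
    for (int j = 0; j <= k; j++)
      S += fact[k] * invfact[j] * invfact[k - j] * pc[k - j] * F[j] * pe[j] *
           pm[k - j];
    G[k] = S;
  }
  return G;
}

// -------------------------------------------------------- series inversion

// Borel-regularized sum of terms[k0..K]: integrate exp(-t) * B(t) over
// (0, inf), B(t) = sum_k terms[k] t^k / k!, with the inner sum truncated at
// K.  Integration stops where the truncated inner sum becomes unreliable;
// ok reports whether the quadrature reached far enough for the e^{-t} tail
// to be negligible.
quad borel_integrate(const std::vector<quad> &terms, int k0, bool &ok,
                     quad &noise) {
  int K = (int)terms.size() - 1;
  const QuadGL &gl = gl_rule(24);
  // the term sequence typically arrives through double-precision logs
  const quad EPSIN = 1e-15;
  quad I = 0, h = 5;
  noise = 0;
  ok = false;
  int small_panels = 0;
  quad t_reached = 0, last_panel = 0;
  for (int p = 0; p < 120; p++) {
    quad a = p * h, c = a + h / 2, hw = h / 2;
    quad panel = 0, pnoise = 0;
    bool invalid = false;
    for (int i = 0; i < 24; i++) {
      quad t = c + hw * gl.x[i];
      quad u = 1, B = 0, maxin = 0;
      for (int k = 1; k <= K; k++) {
        u *= t / k;
        if (k >= k0) {
          quad term = terms[k] * u;
          B += term;
          quad m = fabsq(term);
          if (m > maxin) maxin = m;
        }
      }
      if (k0 == 0) B += terms[0];
      // truncation of the inner sum must be deep in the tail at this t
      quad lastmag = fabsq(terms[K]) * u;
      if (lastmag > 1e-12Q * (maxin + 1e-4932Q)) {
        invalid = true;
        break;
      }
      panel += hw * gl.w[i] * expq(-t) * B;
      quad nz = EPSIN * maxin * expq(-t) * h;
      if (nz > pnoise) pnoise = nz;
    }
    if (invalid) break;
    I += panel;
    t_reached = a + h;
    last_panel = panel;
    if (pnoise > noise) noise = pnoise;
    // stop when panels fall below the resolvable floor: either the
    // relative target or the noise inherited from the input precision
    quad floorv = 1e-18Q * (fabsq(I) + 1e-300Q);
    if (2 * pnoise > floorv) floorv = 2 * pnoise;
    if (fabsq(panel) < floorv) {
      if (++small_panels >= 2) {
        ok = true;
        break;
      }
    } else {
      small_panels = 0;
    }
  }
  // reaching far out with a negligible last panel also counts as converged
  // (the inner truncation stopped the sweep, but the tail is resolved)
  if (!ok && t_reached >= 40 &&
      fabsq(last_panel) < 1e-9Q * (fabsq(I) + 1e-300Q))
    ok = true;
  return I;
}

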