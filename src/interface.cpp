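#include <Rcpp.h>
#include "quadcore.h"
#include "hpcore.h"
using namespace Rcpp;

static DivModel make_model(int family, NumericVector params,
                           Nullable<List> tab = R_NilValue) {
  DivModel m;
  m.family = family;
  m.p1 = params.size() > 0 ? params[0] : 0.0;
  m.p2 = params.size() > 1 ? params[1] : 0.0;
  m.p3 = params.size() > 2 ? params[2] : 0.0;
  if (family == 7) {
    if (tab.isNull()) stop("custom family needs tabulated quadrature");
    List tl(tab);
    m.tab_t = as<std::vector<double>>(tl["t"]);
    m.tab_w = as<std::vector<double>>(tl["w"]);
    m.tab_g = as<std::vector<double>>(tl["g"]);
  }
  return m;
}

// signed natural-log representation
static List signed_log_quad(const std::vector<quad> &v) {
  int n = v.size();
  IntegerVector sgn(n);
  NumericVector lg(n);
  for (int i = 0; i < n; i++) {
    if (v[i] == 0) {
      sgn[i] = 0;
      lg[i] = R_NegInf;
    } else {
      sgn[i] = v[i] > 0 ? 1 : -1;
      lg[i] = (double)logq(fabsq(v[i]));
    }
  }
  return List::create(_["sign"] = sgn, _["loge"] = lg);
}

static List signed_log_hp(const std::vector<HP> &v) {
  int n = v.size();
  IntegerVector sgn(n);
  NumericVector lg(n);
  for (int i = 0; i < n; i++) {
    if (v[i].isZero()) {
      sgn[i] = 0;
      lg[i] = R_NegInf;
    } else {
      sgn[i] = v[i].sign;
      lg[i] = v[i].log2abs() * M_LN2;
    }
  }
  return List::create(_["sign"] = sgn, _["loge"] = lg);
}

// [[Rcpp::export]]
List cpp_gl_nodes(int n) {
  const QuadGL &gl = gl_rule(n);
  NumericVector x(n), w(n);
  for (int i = 0; i < n; i++) {
    x[i] = (double)gl.x[i];
    w[i] = (double)gl.w[i];
  }
  return List::create(_["x"] = x, _["w"] = w);
}

// [[Rcpp::export]]
List cpp_hp_selftest(int limbs) {
  int old = HP::NL;
  HP::setPrecision(limbs);
  // (1/3 * 3 - 1), exp(1)*exp(-1) - 1, sqrt(2)^2 - 2, pi and ln2 vs doubles
  HP third = HP(1.0).divSmall(3);
  double r1 = (third.mulSmall(3) - HP(1.0)).log2abs();
  double r2 = (HP::exp(HP(1.0)) * HP::exp(HP(-1.0)) - HP(1.0)).log2abs();
  HP s2 = HP::sqrt(HP(2.0));
  double r3 = (s2 * s2 - HP(2.0)).log2abs();
  double pi_err = HP::pi().toDouble() - M_PI;
  double ln2_err = HP::ln2().toDouble() - M_LN2;
  // big-exponent round trip: 2^4000 / 2^4000
  HP big = HP::pow2(4000);
  double r4 = (big * HP::recip(big) - HP(1.0)).log2abs();
  // exp at a large negative argument vs quad
  double r5 = HP::exp(HP(-700.0)).log2abs() - (-700.0 / M_LN2);
  HP::setPrecision(old);
  return List::create(_["log2_third"] = r1, _["log2_expid"] = r2,
                      _["log2_sqrt"] = r3, _["pi_err"] = pi_err,
                      _["ln2_err"] = ln2_err, _["log2_big"] = r4,
                      _["log2_expneg"] = r5);
}

// [[Rcpp::export]]
void cpp_set_precision(int limbs) { HP::setPrecision(limbs); }

// [[Rcpp::export]]
NumericVector cpp_laplace(int family, NumericVector params, NumericVector s,
                          Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  NumericVector out(s.size());
  for (int i = 0; i < s.size(); i++) out[i] = (double)m.laplace(quad(s[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_density(int family, NumericVector params, NumericVector t) {
  DivModel m = make_model(family, params);
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); i++) out[i] = (double)m.density(quad(t[i]));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_psi(int family, NumericVector params, double gamma, int K,
                      Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  std::vector<std::vector<quad>> P = psi_matrix(m, quad(gamma), K);
  NumericMatrix out(K + 1, K + 1);
  for (int k = 0; k <= K; k++)
    for (int j = 0; j <= k; j++) out(k, j) = (double)P[k][j];
  return out;
}

// [[Rcpp::export]]
List cpp_mrna_table(int family, NumericVector params, double km, double gm,
                    int K, Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  return signed_log_quad(mrna_coeffs(m, km, gm, K));
}

// [[Rcpp::export]]
List cpp_protein_table(int family, NumericVector params, double a, double b,
                       double gp, int K, Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  return signed_log_hp(protein_coeffs_hp(m, a, b, gp, K));
}

// [[Rcpp::export]]
List cpp_age_table(int species, int family, NumericVector params, double km,
                   double gm, double a, double b, double gp, double tau, int K,
                   Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  if (species == 1) {
    std::vector<quad> F = mrna_coeffs(m, km, gm, K);
    return signed_log_quad(mrna_age_coeffs(F, km, gm, tau));
  }
  std::vector<HP> F = protein_coeffs_hp(m, a, b, gp, K);
  return signed_log_hp(protein_age_coeffs_hp(F, a, b, gp, tau));
}

static std::vector<HP> promote_quad(const std::vector<quad> &v) {
  std::vector<HP> out(v.size());
  for (size_t i = 0; i < v.size(); i++) out[i] = hp_from_quad(v[i]);
  return out;
}

// Full pipeline: state: 1 birth, 2 pre-division, 3 age tau.  mRNA runs the
// quad recursion + HP series inversion; protein runs the level-2 peeled
// HP assembly.  K doubles until the PMF mass over 0..ymax is within
// norm_tol of 1.
// [[Rcpp::export]]
List cpp_pmf(int species, int family, NumericVector params, double km,
             double gm, double a, double b, double gp, int state, double tau,
             int ymax, int K_init, int K_max, double norm_tol,
             Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  int K = K_init;
  InvResult res;
  double norm = 0;
  while (true) {
    if (species == 1) {
      std::vector<quad> C = mrna_coeffs(m, km, gm, K);
      if (state == 3) C = mrna_age_coeffs(C, km, gm, tau);
      double factor = (state == 2) ? 2.0 : 1.0;
      std::vector<HP> Ch(C.size());
      for (size_t i = 0; i < C.size(); i++) Ch[i] = hp_from_quad(C[i]);
      res = invert_series_hp(Ch, factor, ymax);
    } else {
      res = protein_pmf_hp(m, a, b, gp, state, tau, ymax, K);
    }
    norm = 0;
    for (double v : res.p) norm += v;
    if (res.converged && std::fabs(1 - norm) <= norm_tol) break;
    if (K >= K_max) break;
    K = std::min(2 * K, K_max);
  }
  return List::create(_["p"] = NumericVector(res.p.begin(), res.p.end()),
                      _["method"] = IntegerVector(res.method.begin(),
                                                  res.method.end()),
                      _["noise"] = NumericVector(res.noise.begin(),
                                                 res.noise.end()),
                      _["K"] = K, _["norm"] = norm,
                      _["converged"] = res.converged);
}

// Age-averaged PMF: the coefficient table (mRNA) or psi2 table (protein) is
// computed once; per quadrature node the age PMF is formed and accumulated
// with its phi weight.
// [[Rcpp::export]]
List cpp_age_averaged_pmf(int species, int family, NumericVector params,
                          double km, double gm, double a, double b, double gp,
                          NumericVector taus, NumericVector wts, int ymax,
                          int K_init, int K_max, double norm_tol,
                          Nullable<List> tab = R_NilValue) {
  DivModel m = make_model(family, params, tab);
  int K = K_init;
  while (true) {
    std::vector<quad> Fq;
    std::vector<HP> psi2;
    if (species == 1)
      Fq = mrna_coeffs(m, km, gm, K);
    else
      psi2 = hp_psi2_for(m, a, b, gp, protein_K_needed(3, ymax, K));
    std::vector<double> acc(ymax + 1, 0.0), noise(ymax + 1, 0.0);
    bool ok = true;
    int method = 1;
    for (int i = 0; i < taus.size(); i++) {
      InvResult r;
      if (species == 1) {
        std::vector<quad> G = mrna_age_coeffs(Fq, km, gm, taus[i]);
        std::vector<HP> Gh(G.size());
        for (size_t j = 0; j < G.size(); j++) Gh[j] = hp_from_quad(G[j]);
        r = invert_series_hp(Gh, 1.0, ymax);
      } else {
        r = assemble_protein_pmf_psi2(psi2, a, b, gp, 3, taus[i], ymax);
      }
      if (!r.converged) {
        ok = false;
        break;
      }
      for (int y = 0; y <= ymax; y++) {
        acc[y] += wts[i] * r.p[y];
        noise[y] += std::fabs(wts[i]) * r.noise[y];
      }
      for (int mm : r.method)
        if (mm != 1) method = mm;
      Rcpp::checkUserInterrupt();
    }
    double norm = 0;
    for (double v : acc) norm += v;
    bool normok = std::fabs(1 - norm) <= norm_tol;
    if ((ok && normok) || K >= K_max) {
      IntegerVector meth(ymax + 1, method);
      return List::create(_["p"] = NumericVector(acc.begin(), acc.end()),
                          _["method"] = meth,
                          _["noise"] = NumericVector(noise.begin(),
                                                     noise.end()),
                          _["K"] = K, _["norm"] = norm,
                          _["converged"] = ok && normok);
    }
    K = std::min(2 * K, K_max);
  }
}

// Borel-regularized sum of a signed-log term sequence (terms for k = 0, 1, ...).
// [[Rcpp::export]]
List cpp_borel_sum(IntegerVector sign, NumericVector logabs) {
  int K = sign.size() - 1;
  std::vector<quad> terms(K + 1, quad(0));
  for (int k = 0; k <= K; k++)
    if (sign[k] != 0) terms[k] = quad(sign[k]) * expq(quad(logabs[k]));
  bool ok;
  quad noise;
  quad v = borel_integrate(terms, 0, ok, noise);
  return List::create(_["value"] = (double)v, _["converged"] = ok,
                      _["noise"] = (double)noise);
}
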