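#ifndef CYCLOSTAT_QUADCORE_H
#define CYCLOSTAT_QUADCORE_H

#include <quadmath.h>
#include <vector>
#include <stdexcept>

typedef __float128 quad;

// Gauss-Legendre rule on [-1, 1], nodes/weights in quadruple precision.
struct QuadGL {
  std::vector<quad> x, w;
};
const QuadGL &gl_rule(int n);

// Quadrature nodes on (0, U) tailored to a division-time density.
struct Nodes {
  std::vector<quad> t, w;
};

// Division-time model. family codes:
// 1 delta, 2 exponential, 3 erlang, 4 beta_exponential,
// 5 growth_rate_heterogeneity, 6 fluctuating_threshold, 7 tabulated (custom)
struct DivModel {
  int family;
  double p1, p2, p3;
  // tabulated quadrature (family 7): nodes, GL weights, density values
  std::vector<double> tab_t, tab_w, tab_g;

  quad density(quad t) const;
  quad laplace(quad s) const;
  Nodes nodes() const;
  Nodes nodes_coarse() const; // lighter rule for smooth t-averages
};

std::vector<std::vector<quad>> psi_matrix(const DivModel &m, quad gamma, int K);

std::vector<quad> mrna_coeffs(const DivModel &m, double km, double gm, int K);
std::vector<quad> mrna_age_coeffs(const std::vector<quad> &F, double km,
                                  double gm, double tau);

// Series inversion result (per-count probabilities + diagnostics).
struct InvResult {
  std::vector<double> p;      // probabilities for y = 0..ymax
  std::vector<int> method;    // 1 direct, 2 continuation
  std::vector<double> noise;  // estimated numerical noise per count
  bool converged;
};

quad borel_integrate(const std::vector<quad> &terms, int k0, bool &ok,
                     quad &noise);

#endif
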