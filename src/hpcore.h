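#ifndef CYCLOSTAT_HPCORE_H
#define CYCLOSTAT_HPCORE_H

#include "hp.h"
#include "quadcore.h"

extern bool g_inv_debug;

// promote a quad value to HP (three-double decomposition, ~1e-48 relative)
HP hp_from_quad(quad x);

// Laplace transform values L_s = L(s * gp), s = 0..K, in full precision for
// the closed-form families; other families fall back to the quad quadrature
// values (the pipeline's accuracy is then bounded by ~1e-33 inputs).
std::vector<HP> hp_laplace_grid(const DivModel &m, double gp, int K);

// Birth-state protein coefficients c_k = F+^(k)(1) (NOT divided by k!).
std::vector<HP> protein_coeffs_hp(const DivModel &m, double a, double b,
                                  double gp, int K);

// Age transform of the protein table (Eq. 31 structure), tau >= 0.
std::vector<HP> protein_age_coeffs_hp(const std::vector<HP> &F, double a,
                                      double b, double gp, double tau);

// Invert a coefficient table (values C_k = G^(k)(1)) into the PMF on
// 0..ymax; factor = 2 selects the pre-division state.
InvResult invert_series_hp(const std::vector<HP> &C, double factor, int ymax);

#endif

// ---- level-2 peeled protein representation ----
// F+(1+x) = (1 - bx/2)^-a (1 - bx/4)^-a Psi2(1+x); Psi2 is analytic well
// beyond the first two generations of division-thinned burst singularities,
// so PMFs at birth, before division, and at any age assemble from
// geometrically convergent series and negative-binomial convolutions.
std::vector<HP> psi2_coeffs_hp(const DivModel &m, double a, double b,
                               double gp, int K);

// PMF for protein states; state: 1 birth, 2 pre-division, 3 age tau.
// K is a lower bound on the psi2 table length (raised per state as needed).
InvResult protein_pmf_hp(const DivModel &m, double a, double b, double gp,
                         int state, double tau, int ymax, int K);
int protein_K_needed(int state, int ymax, int K_req);
std::vector<HP> hp_psi2_for(const DivModel &m, double a, double b, double gp,
                            int K);
InvResult assemble_protein_pmf_psi2(const std::vector<HP> &psi2, double a,
                                    double b, double gp, int state, double tau,
                                    int ymax);
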