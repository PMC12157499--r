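# cyclostat

Exact cyclo-stationary copy-number distributions of mRNA and bursty protein
in growing and dividing cell lineages, for **arbitrary uncorrelated random
division-time distributions**.

## The problem

Single-cell mRNA and protein counts fluctuate because of gene-expression
noise, because molecules partition binomially between daughters at division,
and because the cell-cycle duration itself is random. After many division
cycles the count distribution at each cell age settles into a
*cyclo-stationary* state. Closed-form results have long existed for fixed
division times, and moment results for Erlang-distributed times, but the
general case of an arbitrary division-time law g(ts) requires a different
route.

`cyclostat` implements an exact series method for that general case. Writing
F₊(q) = Σ_y P₊(y) q^y for the generating function of the copy number just
after division, the coefficients F₊⁽ᵏ⁾(1) (the factorial moments at birth)
obey exact linear recursions whose inputs are integral transforms of g(ts):

- **mRNA** (production at rate km, decay at γm):
  F₊⁽ᵏ⁾(1) = 2⁻ᵏ Σ_{j≤k} C(k,j) (km/γm)^{k−j} Ψ_{k,j} F₊⁽ʲ⁾(1), with
  Ψ_{k,j} = ∫ g(ts) e^{−jγm ts} (1 − e^{−γm ts})^{k−j} dts;
- **protein** (geometric bursts of mean b arriving at rate km, decay at γp,
  a = km/γp): a double-sum recursion whose only dependence on g(ts) is
  through the Laplace-transform values L_s = ∫ g(ts) e^{−s γp ts} dts.

The package inverts these coefficient tables into probability mass
functions at birth, just before division, at any cell age τ, and averaged
over the Powell population-age density φ(τ) = 2 v_m e^{−v_m τ} P(ts > τ)
with 2 L(v_m) = 1. Closed-form CV² expressions and an additive decomposition
of the protein noise into binomial-partitioning (BP), division-time (DT) and
gene-expression (GE) components are included, as is an independent kinetic
Monte Carlo (SSA) lineage simulator used as a validation oracle.

Built-in division-time families: fixed times, exponential, Erlang, the
beta-exponential first-passage law of autocatalytic threshold crossing,
growth-rate heterogeneity, fluctuating-threshold laws, and user-supplied
densities.

The alternating series behind the PMFs lose enormous numbers of digits to
cancellation (the protein generating function has an order-a branch point at
finite distance), so the protein pipeline runs in an arbitrary-precision
big-float arithmetic (~150 significant digits) built into the package, with
the generating function factorized into explicit negative-binomial kernels
times a rapidly convergent residual series. Details are in the methods
vignette (`vignettes/cyclostationary-methods.Rmd`).

## Worked example

Protein noise for Erlang-distributed division times (3 stages, mean 20 min)
at burst arrival km = 0.5/min, burst size b = 2, decay γp = 0.01/min
(a = 50):

```r
library(cyclostat)
pars  <- geneParams(km = 0.5, b = 2, gammaP = 0.01)   # a = km/gammaP = 50
model <- erlangModel(N = 3, lambda = 0.15)            # mean 20 min, CV^2 = 1/3

decomposeProteinNoise(pars, model)
#> Protein noise decomposition (CV^2 at birth):
#>   total 0.2293 = BP 0.0403 + DT 0.0781 + GE 0.1108
#>   shares: BP 18%, DT 34%, GE 48%

tab <- proteinCoefficients(pars, model, K = 400)
cumulants(tab)
#> NoiseSummary:
#>   mean 14.9678, variance 51.3661, kappa3 285.802
#>   CV^2 0.229277, skewness 0.776335

pmf <- pmfAtBirth(tab)
pmf
#> PMFResult: state 'birth', support 0..73, method factorized
#>   total mass 0.99999985 (K = 400, 0 negatives clipped)
```

A third of the protein noise at these parameters is caused purely by the
randomness of the cell-cycle duration (DT), and would be missed by a
fixed-division-time analysis. The analytic PMF is confirmed by the
independent stochastic simulation:

```r
set.seed(1)
sim <- simulateLineage(simConfig("protein", pars, model, nHistories = 5000,
                                 burnInCycles = 40, recordCycles = 4))
totalVariation(sim$birth, pmf)
#> [1] 0.01847776   # consistent with 2e4 Monte Carlo samples
```

Age-resolved and age-averaged distributions follow the same pattern
(`pmfAtAge`, `powellAgeWeight`, `ageAveragedPmf`), and
`inst/scripts/cyclostat` exposes the pipeline as a command-line tool driven
by YAML/JSON configurations.

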