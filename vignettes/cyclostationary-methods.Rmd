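---
title: "Methods: exact cyclo-stationary copy-number distributions for random division times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact cyclo-stationary copy-number distributions for random division times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclostat)
```

## The model

A single gene expresses either mRNA (production at rate $k_m$, first-order
decay at $\gamma_m$) or, in the bursty reduction valid when mRNA turns over
much faster than protein, protein arriving in geometric bursts
$P(r) = b^r/(1+b)^{1+r}$ at rate $k_m$ with decay $\gamma_p$. The cell
divides after a random time $t_s \sim g(t_s)$, independent across cycles,
and each molecule goes to the followed daughter independently with
probability $1/2$. After many cycles the count distribution at every fixed
cell age becomes stationary (the *cyclo-stationary* state). All times are
minutes and rates $\mathrm{min}^{-1}$ throughout.

The central objects are the derivatives at $q = 1$ of the birth-state
generating function $F_+(q)$, i.e. the factorial moments at birth. The fixed
point $q = 1$ of the map $q \mapsto 1 + (q-1)e^{-\gamma t}/2$ appearing in
the cycle-to-cycle functional equation makes these coefficients satisfy
exact linear recursions:

* **mRNA.** $F_+^{(k)}(1) = 2^{-k} \sum_{j \le k} \binom{k}{j}
  (k_m/\gamma_m)^{k-j}\, \Psi_{k,j}\, F_+^{(j)}(1)$, where
  $\Psi_{k,j} = \int_0^\infty g(t)\, e^{-j\gamma_m t}
  (1 - e^{-\gamma_m t})^{k-j}\, dt$.
* **Protein.** A double sum over the burst structure whose only dependence
  on $g$ is through Laplace values $L_s = \int g(t) e^{-s\gamma_p t} dt$.
  The package evaluates it in the exactly equivalent collapsed form
  $F_k (1 - 2^{-k} L_k) = a\,k!\,2^{-k} \big[\sum_{s<k} L_s\, b^{k-s}
  A_{k-s} D_s/(k-s)! + L_k (D_k - c_k)/a\big]$ with
  $c_j = F_j/j!$, $D_s = \sum_l \binom{a}{l} (-b)^l c_{s-l}$ and
  $A_m = \Gamma(a+m)/\Gamma(a+1)$, which is both $O(K^2)$ and keeps the
  alternating part confined to a single convolution.

In both cases the $j = k$ (resp. $s = k$) term contains the unknown and is
moved to the left-hand side, so each order is obtained by one linear solve —
no fixed-point iteration is involved. The binomial partition probability is
fixed at $1/2$; asymmetric division is out of scope.

PMFs follow by inverting the coefficient table: at birth
$P_+(y) = \sum_{k \ge y} \binom{k}{y} (-1)^{k-y} F_k / k!$, before division
the same with $2^k F_k$ (since $F_-(q) = F_+(2q-1)$), and at age $\tau$ with
age-propagated coefficients $G^{(k)}(\tau)$ that reduce to $F_k$ at
$\tau = 0$. The first three cumulants come directly from $F_1, F_2, F_3$
with no truncation. The age-averaged distribution integrates the age-
resolved PMFs against the Powell population-age density
$\phi(\tau) = 2 v_m e^{-v_m\tau} \Pr(t_s > \tau)$, where $v_m$ solves
$2L(v_m) = 1$; we obtain $v_m$ by a bracketed root search on the monotone
Laplace transform (bracket $(\varepsilon,\ 10\ln 2/\langle t_s\rangle)$) and
confirm the Erlang closed form $v_m = \lambda(2^{1/N} - 1)$ against it.

## Division-time families and their parameters

| family | parameters | mean | CV² |
|---|---|---|---|
| `delta` | $T$ | $T$ | $0$ |
| `exponential` | mean $T$ | $T$ | $1$ |
| `erlang` | shape $N$, rate $\lambda$ | $N/\lambda$ | $1/N$ |
| `beta_exponential` | threshold $X$, start $n_0$, rate $\beta$ | $\tfrac1\beta\sum_{s=n_0}^{X-1}\tfrac1s$ | $\sum 1/s^2 / (\sum 1/s)^2$ |
| `growth_rate_heterogeneity` | $\beta_0$, $\sigma_\beta$ | numeric | numeric |
| `fluctuating_threshold` | $\beta_0$, $\sigma_\beta$, $\sigma_X$ | numeric | numeric |

The beta-exponential law is the first-passage time of an autocatalytic
birth process from $n_0$ to a threshold $X$: a hypoexponential sum of
$X - n_0$ stages with rates $\beta s$, whose mean is the harmonic sum above
(`calibrateBetaExponential()` solves it for $\beta$; at $X = 20$,
$n_0 = 10$ and mean 20 min this gives CV² ≈ 0.104). The growth-rate
heterogeneity law is $t_s = \ln 2/\beta$ with Gaussian $\beta$; the
fluctuating-threshold law additionally randomizes $\ln(X/n_0)$ with
variance $\sigma_X^2$. Both are evaluated from their elementary closed-form
densities; their far tail decays only algebraically (with an exponentially
small prefactor), so moments are computed on a truncated domain chosen from
the Gaussian exponent, and the residual tail mass (≲ 1e-10 at the reference
parameters) is simply reported through the normalization diagnostics.

The delta family is represented symbolically: its moments, Laplace
transform and $\Psi$ integrals use closed forms, and `dtDensity()` refuses
to evaluate a Dirac density rather than approximate it.

$\Psi_{k,j}$ is computed by quadrature of its *non-negative* integrand
rather than by the alternating binomial expansion into Laplace values: the
expansion loses up to $2^{k-j}$ in cancellation, while the direct integrand
is positive and smooth. The quadrature uses logarithmically spaced
Gauss–Legendre panels near $t = 0$ — the factor
$(1-e^{-\gamma t})^{k-j}$ behaves like $(\gamma t)^{k-j}$ there and rises on
the scale $\ln(k)/\gamma$ — plus linear panels a few decay lengths wide in
the exponential tail. The expansion route is retained as a cross-check in
the unit tests (agreement ≤ 1e-8 for $k \le 10$).

## Numerical design

**Why high precision.** The inversion series are alternating, and the
protein generating function has a branch point of order $a = k_m/\gamma_p$
at finite distance from the expansion point, so for physiological $a \sim
50$ every evaluation route passes through intermediate terms tens to
hundreds of orders of magnitude larger than the result. Double (16 digits)
and even quadruple precision (34 digits) are insufficient. The package
therefore ships a small fixed-precision binary big-float arithmetic
(`src/hp.*`; 32-bit limbs, runtime-settable precision, default 18 limbs ≈
165 decimal digits) implementing exactly the operations the pipeline needs:
field operations (division via Newton reciprocal), `sqrt`, `exp` (argument
reduction against a series-computed $\ln 2$), `ln`, and a series-computed
$\pi$. All gamma-ratio factors in the recursions are Pochhammer *products*,
so no high-precision gamma function is required; for non-integer $a$ the
products pass smoothly through the reciprocal-gamma convention (factors
with $l > a$ vanish at integer $a$), and the tests verify continuity of the
coefficients across integer $a$. The mRNA side, whose generating function
is entire and whose recursion has only positive terms, runs in
`__float128`.

**Protein PMFs by factorized assembly.** Direct summation of the inversion
series diverges polynomially at the evaluation point for the protein case
(the series sits exactly on its circle of convergence). Instead of
regularizing the divergent sum, the package peels the two leading
generations of division-thinned burst singularities off analytically:
$$F_+(1+x) = (1 - bx/2)^{-a} (1 - bx/4)^{-a}\, \Psi_2(1+x),$$
where $\Psi_2$ satisfies its own exact recursion (driven by the same
$L_s$ values and a kernel with a stable three-term recurrence) and is
analytic well beyond the evaluation region — empirically its Taylor
coefficients decay like $3^{-k}$ for the reference models. Every PMF then
assembles from geometrically convergent series and convolutions with
explicit negative-binomial kernels:

* birth: $\mathrm{NB}(b/2) * \mathrm{NB}(b/4) * \Psi_2$-series;
* age $\tau$: $\mathrm{NB}(b) * (1+bE-bEq)^{+a} * \mathrm{NB}(bE/2) *
  \mathrm{NB}(bE/4) * \Psi_2$-series with $E = e^{-\gamma_p\tau}$
  (at $\tau = 0$ the exactly cancelling pair is skipped);
* pre-division: the age-$t_s$ PMF averaged over $g(t_s)$ — the cell caught
  just before division has age exactly $t_s$ — using a dedicated
  Gauss–Legendre rule over the division-time density.

Borel summation, the classical alternative for such series, is implemented
and exposed as `borelSum()` (validated on geometrically damped and
Poisson-type term sequences); it is not used as the default PMF fallback
because its integrand legitimately peaks near $e^{a\ln(a/2)-a}$ for the
protein case, which would demand far more working precision than the
factorized assembly.

**Truncation and convergence control.** Coefficient tables default to
$K = 200$ (mRNA) and $K = 400$ (protein); the inversion doubles $K$ (up to
700) until every count converges and the total mass over the requested
support is within `normTol` (default 1e-4) of 1. The support defaults to
mean $+ 8$ standard deviations from the exact cumulants, so the
normalization check is meaningful. Per-count numerical-noise estimates and
the summation method are recorded in the `convergence` slot; negative
values below 1e-8 in magnitude are clipped to zero and counted, larger ones
raise an error rather than being silently repaired. Requests for more
working precision than the arithmetic provides raise an explicit error.

**Age averaging.** $\int \phi(\tau) P(y,\tau)\, d\tau$ uses 64
Gauss–Legendre nodes (48 suffice for the protein runs in the test-suite) on
$(0, \tau_{max})$ with $\tau_{max}$ at survival $< 10^{-10}$; the
coefficient (or $\Psi_2$) table is computed once and only the cheap age
transform and assembly run per node. For the delta family the weight
reduces to the classical fixed-$T$ age density
$(\ln 2/T)\,2^{1-\tau/T}$ on $[0,T]$, which the tests exploit as an
independent integral oracle.

## The simulator

`simulateLineage()` is an exact direct-method SSA over a single followed
daughter: within a cycle, mRNA birth/death or bursty protein
production/decay; at division, a $\mathrm{Binomial}(y, 1/2)$ draw selects
the followed cell. Defaults: 100 burn-in cycles (the initial condition is
forgotten geometrically through the halving at division; the test-suite
uses 25–50), one recorded cycle per history. Age snapshots at age $\tau$
are recorded only in cycles with $t_s > \tau$, matching the conditioning of
the age-resolved analytics on survival to that age (the alternative —
re-drawing short cycles — would bias the division-time mixture). Successive
division times can be AR(1)-correlated,
$t_{s,i} = (1-\epsilon)\,\mathrm{draw} + \epsilon\, t_{s,i-1}$, which
preserves the long-run mean and gives lag-1 autocorrelation $\epsilon$;
with $\epsilon > 0$ the simulated distributions deviate from the
uncorrelated analytics, more strongly for protein than mRNA. Division
times are drawn structurally (Erlang as stage sums, beta-exponential as
its first-passage stage sum, growth-rate heterogeneity as $\ln 2/\beta$)
or by inverse-CDF lookup on a quadrature-derived grid
(fluctuating-threshold, custom). The simulator shares no code with the
analytic pipeline beyond the division-time model definitions, which is
what makes the total-variation comparisons in the tests a genuine
two-sided validation.

What the simulator (and hence the generator-based tests) does *not*
emulate: population trees (a single daughter is followed), mRNA–protein
coupling (the bursty reduction is simulated directly, as in the analytic
model), cell-size-dependent rates, and gene replication during the cycle.
Agreement between the two pipelines therefore validates the mathematics of
the series solution, not those biological extensions.

## Choices on ambiguous points

* The beta-exponential mean is the harmonic sum (see above).
* The Erlang growth exponent $v_m = \lambda(2^{1/N}-1)$ is validated
  against the implicit equation $2L(v_m)=1$ rather than assumed.
* The closed-form CV² expressions (and the BP/DT/GE decomposition) are
  implemented from first principles — $F_1$ and $F_2$ derived symbolically
  from the recursions — and are required by the tests to agree with the
  independent cumulant pipeline to 1e-10; the decomposition is additive by
  construction and its gene-expression component is cross-checked against
  the subtraction route with an internal-consistency error beyond 1e-6.
  This double bookkeeping removes any transcription ambiguity in the
  grouping of terms.
* Burst arrival rate is taken to be $k_m$ itself (the "effective rate"
  annotation in the model schematic is not given an independent value).
* Percentage noise shares are stored at full precision and rounded only
  for display.

## Limitations

* Families without closed-form Laplace transforms (growth-rate
  heterogeneity, fluctuating threshold, custom) enter the protein pipeline
  through quadrature values of ~1e-15–1e-33 relative accuracy, which bounds
  the achievable PMF accuracy for them; the reference families (delta,
  exponential, Erlang, beta-exponential) are evaluated fully in high
  precision.
* Very large $a$ (≫ 10²) or very large supports raise the precision and
  table-length requirements; the defaults are sized for the desk-scale
  regimes exercised here ($a \le 50$, means ≤ ~30 at birth). The
  convergence diagnostics fail loudly, never silently, outside them.
* Gene duplication, dosage compensation, promoter switching,
  size-dependent expression and concentration-based models are out of
  scope, as are fits of $g(t_s)$ to data.

## Problem sizes in the tests

The unit and validation tests run at desk scale by design: coefficient
tables to $K \le 400$, supports to ~140 counts, simulations of 1e5 recorded
cycles (2×10⁴ histories × 5 cycles after 40 burn-in) for the
total-variation checks (TV < 0.02 against the analytic PMFs), and 3–4×10⁴
draws for sampler moment checks. The complete suite runs in under three
minutes on one CPU.
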