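#' @title Division-time distribution model
#'
#' @description An S4 container for the probability law of the cell-cycle
#' duration. Built-in families: `delta` (fixed time), `exponential`,
#' `erlang`, `beta_exponential` (first passage of an autocatalytic growth
#' process over a fixed threshold), `growth_rate_heterogeneity`
#' (deterministic exponential growth at a Gaussian-distributed rate), and
#' `fluctuating_threshold` (exponential growth against a log-normally
#' fluctuating threshold). `custom` wraps a user-supplied density.
#'
#' @slot family character; one of the family names above.
#' @slot params named numeric vector of family parameters.
#' @slot density density function for `custom` models (otherwise `NULL`).
#' @slot sampler optional sampler function for `custom` models.
#' @slot upper numeric; upper quadrature limit for `custom` models.
#'
#' @seealso [divisionTimeModel()], [dtDensity()], [dtMoments()], [dtLaplace()]
#' @export
setClass("DivisionTimeModel",
  representation(family = "character", params = "numeric", density = "ANY",
                 sampler = "ANY", upper = "numeric"),
  prototype(density = NULL, sampler = NULL, upper = NA_real_))

.dtFamilies <- c(delta = 1L, exponential = 2L, erlang = 3L,
                 beta_exponential = 4L, growth_rate_heterogeneity = 5L,
                 fluctuating_threshold = 6L, custom = 7L)

setValidity("DivisionTimeModel", function(object) {
  fam <- object@family
  p <- object@params
  if (length(fam) != 1L || !fam %in% names(.dtFamilies))
    return(sprintf("unknown family '%s'", paste(fam, collapse = ",")))
  need <- function(nm) all(nm %in% names(p))
  msg <- switch(fam,
    delta = if (!need("T") || p[["T"]] <= 0) "delta needs T > 0",
    exponential = if (!need("T") || p[["T"]] <= 0)
      "exponential needs mean T > 0",
    erlang = {
      if (!need(c("N", "lambda"))) "erlang needs N and lambda"
      else if (p[["N"]] < 1 || p[["N"]] != round(p[["N"]]))
        "erlang shape N must be a positive integer"
      else if (p[["lambda"]] <= 0) "erlang rate lambda must be > 0"
    },
    beta_exponential = {
      if (!need(c("X", "n0", "beta"))) "beta_exponential needs X, n0, beta"
      else if (p[["X"]] != round(p[["X"]]) || p[["n0"]] != round(p[["n0"]]))
        "X and n0 must be integers"
      else if (p[["n0"]] <= 0 || p[["n0"]] >= p[["X"]])
        "need 0 < n0 < X"
      else if (p[["beta"]] <= 0) "growth rate beta must be > 0"
    },
    growth_rate_heterogeneity = {
      if (!need(c("beta0", "sigma_beta")))
        "growth_rate_heterogeneity needs beta0, sigma_beta"
      else if (p[["beta0"]] <= 0 || p[["sigma_beta"]] <= 0)
        "need beta0 > 0 and sigma_beta > 0"
    },
    fluctuating_threshold = {
      if (!need(c("beta0", "sigma_beta", "sigma_X")))
        "fluctuating_threshold needs beta0, sigma_beta, sigma_X"
      else if (p[["beta0"]] <= 0) "need beta0 > 0"
      else if (p[["sigma_beta"]] < 0 || p[["sigma_X"]] < 0)
        "need sigma_beta >= 0 and sigma_X >= 0"
      else if (p[["sigma_beta"]] == 0 && p[["sigma_X"]] == 0)
        "at least one of sigma_beta, sigma_X must be positive"
    },
    custom = {
      if (!is.function(object@density)) "custom model needs a density function"
      else if (!is.finite(object@upper) || object@upper <= 0)
        "custom model needs a finite positive 'upper' quadrature limit"
    })
  if (is.null(msg) || isTRUE(is.na(msg))) TRUE else msg
})

#' Kinetic parameters of the gene-expression model
#'
#' Transcription (or burst-arrival) rate `km`, mRNA decay rate `gammaM`, mean
#' geometric burst size `b`, and protein decay rate `gammaP`. All rates are
#' in reciprocal minutes. The dimensionless mean-setting ratio
#' `a = km / gammaP` is available through [aRatio()]. Fields not needed by a
#' given species may be left `NA`.
#'
#' @slot km transcription / burst-arrival rate (1/min).
#' @slot gammaM mRNA decay rate (1/min).
#' @slot b mean burst size (dimensionless).
#' @slot gammaP protein decay rate (1/min).
#' @seealso [geneParams()]
#' @export
setClass("GeneParams",
  representation(km = "numeric", gammaM = "numeric", b = "numeric",
                 gammaP = "numeric"))

setValidity("GeneParams", function(object) {
  chk <- function(x, nm, lo) {
    if (length(x) != 1L) return(sprintf("%s must be a single number", nm))
    if (!is.na(x) && x < lo) return(sprintf("%s out of range", nm))
    NULL
  }
  # km = 0 describes an empty (silent) gene and is allowed
  for (nm in c("gammaM", "b", "gammaP")) {
    m <- chk(slot(object, nm), nm, .Machine$double.xmin)
    if (!is.null(m)) return(m)
  }
  m <- chk(object@km, "km", 0)
  if (!is.null(m)) return(m)
  if (is.na(object@km)) return("km is required")
  TRUE
})

#' Table of generating-function derivatives at q = 1
#'
#' Holds the factorial-moment coefficients of the birth-state (or, after
#' [ageCoefficients()], age-tau) generating function, in a magnitude-safe
#' signed-log representation: coefficient k equals `sign[k+1] *
#' exp(loge[k+1])`. The originating kinetic parameters and division-time
#' model are kept so that downstream operations can re-run the full
#' quadruple-precision pipeline rather than relying on the double-precision
#' logs stored here.
#'
#' @slot species "mrna" or "protein".
#' @slot K truncation order; coefficients k = 0..K are stored.
#' @slot sign integer vector of signs.
#' @slot loge natural-log magnitudes.
#' @slot params a [GeneParams-class] object.
#' @slot model a [DivisionTimeModel-class] object.
#' @slot age cell age tau of the table (`NA` for the birth-state table).
#' @slot precision approximate working precision in decimal digits.
#' @seealso [mrnaCoefficients()], [proteinCoefficients()], [pmfAtBirth()]
#' @export
setClass("CoefficientTable",
  representation(species = "character", K = "integer", sign = "integer",
                 loge = "numeric", params = "GeneParams",
                 model = "DivisionTimeModel", age = "numeric",
                 precision = "numeric"),
  prototype(age = NA_real_, precision = 33))

setValidity("CoefficientTable", function(object) {
  if (!object@species %in% c("mrna", "protein"))
    return("species must be 'mrna' or 'protein'")
  if (length(object@sign) != object@K + 1L ||
      length(object@loge) != object@K + 1L)
    return("sign/loge must have length K + 1")
  if (object@sign[1L] != 1L || abs(object@loge[1L]) > 1e-10)
    return("normalization violated: coefficient 0 must equal 1")
  TRUE
})

#' Probability mass function with convergence metadata
#'
#' @slot support integer counts 0..ymax.
#' @slot probabilities per-count probabilities (clipped to \[0, 1\]).
#' @slot state one of "birth", "pre_division", "age", "age_averaged".
#' @slot age cell age (minutes) for state "age", else `NA`.
#' @slot method "direct", "borel" or "mixed" summation.
#' @slot convergence list: per-count numerical-noise estimates, per-count
#'   method codes, truncation order used, normalization deficit, and the
#'   number of small negative values clipped to zero.
#' @export
setClass("PMFResult",
  representation(support = "integer", probabilities = "numeric",
                 state = "character", age = "numeric", method = "character",
                 convergence = "list"),
  prototype(age = NA_real_))

setValidity("PMFResult", function(object) {
  if (length(object@support) != length(object@probabilities))
    return("support and probabilities differ in length")
  if (any(object@probabilities < 0) || any(object@probabilities > 1 + 1e-8))
    return("probabilities outside [0, 1]")
  TRUE
})

#' First three cumulants and derived noise measures
#'
#' @slot mean first cumulant of the copy-number distribution.
#' @slot variance second cumulant.
#' @slot kappa3 third cumulant.
#' @slot cv2 squared coefficient of variation, variance / mean^2.
#' @slot skewness kappa3 / variance^(3/2).
#' @export
setClass("NoiseSummary",
  representation(mean = "numeric", variance = "numeric", kappa3 = "numeric",
                 cv2 = "numeric", skewness = "numeric"))

#' Additive decomposition of protein noise
#'
#' Splits the total squared coefficient of variation of the protein count at
#' birth into binomial-partitioning (BP), division-time (DT) and
#' gene-expression (GE) components; the three add up to the total exactly.
#'
#' @slot cv2Total total CV^2.
#' @slot cv2BP binomial-partitioning component.
#' @slot cv2DT division-time component (zero for fixed division times).
#' @slot cv2GE gene-expression component.
#' @slot shares percentage shares of BP/DT/GE (full precision).
#' @export
setClass("DecompositionResult",
  representation(cv2Total = "numeric", cv2BP = "numeric", cv2DT = "numeric",
                 cv2GE = "numeric", shares = "numeric"))

#' Population age weight of Powell
#'
#' The cell-age density in an exponentially growing population,
#' `phi(tau) = 2 vm exp(-vm tau) P(ts > tau)`, with the population growth
#' exponent `vm` solving `2 L(vm) = 1` where `L` is the Laplace transform of
#' the division-time density.
#'
#' @slot vm population growth exponent (1/min).
#' @slot survival function returning `P(ts > tau)`.
#' @slot model the underlying [DivisionTimeModel-class].
#' @slot normCheck numerically computed integral of phi (should be ~1).
#' @export
setClass("AgeWeight",
  representation(vm = "numeric", survival = "function",
                 model = "DivisionTimeModel", normCheck = "numeric"))

#' Configuration of a lineage simulation
#'
#' @slot species "mrna" or "protein".
#' @slot params [GeneParams-class] kinetic rates.
#' @slot model [DivisionTimeModel-class] division-time law.
#' @slot nHistories number of independent lineages.
#' @slot burnInCycles division cycles discarded before recording.
#' @slot recordCycles recorded cycles per history.
#' @slot ages cell ages (minutes) at which to record age snapshots.
#' @slot eps AR(1) correlation parameter of successive division times.
#' @export
setClass("SimConfig",
  representation(species = "character", params = "GeneParams",
                 model = "DivisionTimeModel", nHistories = "integer",
                 burnInCycles = "integer", recordCycles = "integer",
                 ages = "numeric", eps = "numeric"))

setValidity("SimConfig", function(object) {
  if (!object@species %in% c("mrna", "protein"))
    return("species must be 'mrna' or 'protein'")
  if (object@nHistories < 1L) return("nHistories must be >= 1")
  if (object@burnInCycles < 1L) return("burnInCycles must be >= 1")
  if (object@recordCycles < 1L) return("recordCycles must be >= 1")
  if (object@eps < 0 || object@eps >= 1) return("eps must be in [0, 1)")
  TRUE
})

#' Histogram of simulated copy numbers
#'
#' @slot counts named integer vector; names are copy numbers.
#' @slot nSamples total number of samples.
#' @slot state recorded state label.
#' @slot age age (minutes) for age-resolved histograms, else `NA`.
#' @export
setClass("CountHistogram",
  representation(counts = "integer", nSamples = "integer", state = "character",
                 age = "numeric"),
  prototype(age = NA_real_))
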