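# Cell-age-resolved distributions: the age-tau coefficient transform, the
# PMF at a fixed age, and the age-averaged PMF under a population age weight.

#' Age-tau coefficient transform
#'
#' Propagates the birth-state coefficients to cell age tau. For mRNA,
#' `G_k(tau) = sum_j C(k,j) (km/gammaM)^{k-j} F_j e^{-j gammaM tau}
#' (1 - e^{-gammaM tau})^{k-j}`; for protein the transform is the
#' double sum over the burst structure with decay factors
#' `e^{-(l+j) gammaP tau}`. At tau = 0 the transform is the identity.
#'
#' @param table a birth-state [CoefficientTable-class].
#' @param tau cell age (minutes), >= 0.
#' @return A [CoefficientTable-class] with the `age` slot set.
#' @export
setMethod("ageCoefficients", "CoefficientTable", function(table, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (!is.na(table@age)) stop("table is already an age-tau table")
  p <- table@params
  raw <- cpp_age_table(if (table@species == "mrna") 1L else 2L,
                       .familyCode(table@model), .familyParams(table@model),
                       p@km, if (is.na(p@gammaM)) 0 else p@gammaM,
                       if (table@species == "protein") aRatio(p) else 0,
                       if (is.na(p@b)) 0 else p@b,
                       if (is.na(p@gammaP)) 0 else p@gammaP,
                       tau, table@K, tab = .modelTab(table@model))
  .newTable(table@species, raw, table@K, p, table@model, age = tau)
})

#' Cyclo-stationary PMF at a fixed cell age
#'
#' @param table a birth-state [CoefficientTable-class].
#' @param tau cell age (minutes) since the last division.
#' @param ymax largest count of the support (default mean + 8 sd at age tau).
#' @param normTol mass tolerance before the truncation order is doubled.
#' @param ... unused.
#' @return A [PMFResult-class] with state `"age"`.
#' @export
setMethod("pmfAtAge", "CoefficientTable",
          function(table, tau, ymax = NULL, normTol = 1e-4, ...) {
  if (tau < 0) stop("tau must be >= 0")
  if (!is.na(table@age)) stop("pass the birth-state table, not an age table")
  if (is.null(ymax)) ymax <- .defaultYmax(ageCoefficients(table, tau), 1)
  res <- .pmfCall(table, 3L, tau, ymax, normTol)
  .asPmf(res, "age", tau, normTol)
})

# upper integration limit for the age quadrature: survival below 1e-10
.tauMax <- function(weight) {
  if (weight@model@family == "delta") return(weight@model@params[["T"]])
  m <- dtMoments(weight@model)[["mean"]]
  hi <- m
  while (weight@survival(hi) > 1e-10 && hi < 400 * m) hi <- hi * 1.5
  hi
}

#' Age-averaged cyclo-stationary PMF
#'
#' Integrates the age-tau PMFs against an age density,
#' `Pbar(y) = int phi(tau) P(y, tau) dtau`, by Gauss-Legendre quadrature
#' over (0, taumax) with taumax where the division-time survival drops below
#' 1e-10. The coefficient table is computed once and only the (cheap)
#' age transform and inversion run per node.
#'
#' @param table a birth-state [CoefficientTable-class].
#' @param weight an [AgeWeight-class], typically from [powellAgeWeight()]
#'   of the same division-time model.
#' @param ymax largest count of the support.
#' @param nNodes number of quadrature nodes (default 64).
#' @param normTol mass tolerance.
#' @param ... unused.
#' @return A [PMFResult-class] with state `"age_averaged"`.
#' @export
setMethod("ageAveragedPmf", "CoefficientTable",
          function(table, weight, ymax = NULL, nNodes = 64L, normTol = 1e-4,
                   ...) {
  if (!is.na(table@age)) stop("pass the birth-state table, not an age table")
  if (is.null(ymax))
    ymax <- max(.defaultYmax(table, 1), .defaultYmax(table, 2))
  tmax <- .tauMax(weight)
  gl <- cpp_gl_nodes(as.integer(nNodes))
  taus <- tmax / 2 * (gl$x + 1)
  wts <- tmax / 2 * gl$w * ageDensity(weight, taus)
  p <- table@params
  species <- if (table@species == "mrna") 1L else 2L
  res <- cpp_age_averaged_pmf(species, .familyCode(table@model),
                              .familyParams(table@model), p@km,
                              if (is.na(p@gammaM)) 0 else p@gammaM,
                              if (species == 2L) aRatio(p) else 0,
                              if (is.na(p@b)) 0 else p@b,
                              if (is.na(p@gammaP)) 0 else p@gammaP,
                              taus, wts, as.integer(ymax), table@K, .KMAX,
                              normTol, tab = .modelTab(table@model))
  if (!res$converged)
    stop("age-averaged inversion did not converge by K = ", res$K)
  .asPmf(res, "age_averaged", NA_real_, normTol)
})
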