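# Inversion of coefficient tables into probability mass functions, and the
# exact cumulants.  Each probability is an alternating series over the
# coefficients; the sums are evaluated in quadruple precision with automatic
# truncation-order doubling, falling back to Borel summation whenever the
# direct partial sums do not stabilize (the protein series can be divergent).

.KMAX <- 700L

.kappas <- function(F1, F2, F3) {
  k1 <- F1
  k2 <- F1 + F2 - k1^2
  k3 <- 3 * F2 + F3 + F1 - 3 * k1 * k2 - k1^3
  c(k1 = k1, k2 = k2, k3 = k3)
}

# first three coefficients of a table, rescaled by `factor^k` (2 for the
# pre-division state)
.tableKappas <- function(table, factor = 1) {
  if (table@K < 3L) stop("cumulants need K >= 3")
  v <- table@sign[2:4] * exp(table@loge[2:4]) * factor^(1:3)
  .kappas(v[1], v[2], v[3])
}

.defaultYmax <- function(table, factor = 1) {
  k <- .tableKappas(table, factor)
  max(10L, as.integer(ceiling(k[["k1"]] + 8 * sqrt(max(k[["k2"]], 1)))))
}

.pmfCall <- function(table, state, tau, ymax, normTol) {
  p <- table@params
  species <- if (table@species == "mrna") 1L else 2L
  res <- cpp_pmf(species, .familyCode(table@model), .familyParams(table@model),
                 p@km, if (is.na(p@gammaM)) 0 else p@gammaM,
                 if (species == 2L) aRatio(p) else 0,
                 if (is.na(p@b)) 0 else p@b,
                 if (is.na(p@gammaP)) 0 else p@gammaP,
                 state, tau, as.integer(ymax), table@K, .KMAX, normTol,
                 tab = .modelTab(table@model))
  if (!res$converged)
    stop("series inversion did not converge by K = ", res$K,
         " (normalization deficit ", signif(1 - res$norm, 3), "); the ",
         "available quadruple precision is insufficient for this parameter ",
         "regime -- reduce the mean copy number or the requested support")
  res
}

.asPmf <- function(res, stateLabel, tau, normTol) {
  p <- res$p
  neg <- p < 0
  if (any(p < -1e-8))
    stop("inversion produced negative probabilities of magnitude ",
         signif(max(-p), 3), "; series not converged")
  nClipped <- sum(neg)
  p[neg] <- 0
  if (abs(1 - sum(p)) > normTol * 1.5)
    warning("PMF mass over the requested support is ", signif(sum(p), 6))
  lab <- c("direct", "continuation", "factorized")
  meth <- if (length(unique(res$method)) == 1L) lab[res$method[1L]]
          else "mixed"
  new("PMFResult", support = seq_along(p) - 1L, probabilities = p,
      state = stateLabel, age = tau, method = meth,
      convergence = list(noise = res$noise, methodPerCount = res$method,
                         K = res$K, normDeficit = 1 - res$norm,
                         nClipped = nClipped))
}

#' Cyclo-stationary PMF at cell birth
#'
#' Inverts the coefficient table through the alternating series
#' `P(y) = sum_{k>=y} C(k,y) (-1)^{k-y} F_k / k!`.
#'
#' @param table a birth-state [CoefficientTable-class].
#' @param ymax largest count of the returned support; defaults to
#'   mean + 8 standard deviations (from the exact cumulants).
#' @param normTol acceptable deviation of the total mass from 1 before the
#'   truncation order is doubled (default 1e-4).
#' @param ... unused.
#' @return A [PMFResult-class].
#' @examples
#' tab <- mrnaCoefficients(geneParams(0.5, gammaM = 0.05), deltaModel(20), K = 60)
#' pmf <- pmfAtBirth(tab)
#' sum(pmf@probabilities)
#' @export
setMethod("pmfAtBirth", "CoefficientTable",
          function(table, ymax = NULL, normTol = 1e-4, ...) {
  if (!is.na(table@age))
    stop("this is an age-tau table; use pmfAtAge() on the birth table")
  if (is.null(ymax)) ymax <- .defaultYmax(table, 1)
  res <- .pmfCall(table, 1L, 0, ymax, normTol)
  .asPmf(res, "birth", NA_real_, normTol)
})

#' Cyclo-stationary PMF just before division
#'
#' Same series as [pmfAtBirth()] with the extra factor `2^k` (the
#' pre-division generating function is `F_-(q) = F_+(2q - 1)`).
#'
#' @inheritParams pmfAtBirth
#' @return A [PMFResult-class].
#' @export
setMethod("pmfBeforeDivision", "CoefficientTable",
          function(table, ymax = NULL, normTol = 1e-4, ...) {
  if (!is.na(table@age))
    stop("this is an age-tau table; use pmfAtAge() on the birth table")
  if (is.null(ymax)) ymax <- .defaultYmax(table, 2)
  res <- .pmfCall(table, 2L, 0, ymax, normTol)
  .asPmf(res, "pre_division", NA_real_, normTol)
})

#' Exact cumulants and noise measures from a coefficient table
#'
#' The first three cumulants follow exactly from the first three
#' coefficients (no series truncation): `kappa1 = F1`,
#' `kappa2 = F1 + F2 - kappa1^2`,
#' `kappa3 = 3 F2 + F3 + F1 - 3 kappa1 kappa2 - kappa1^3`.
#'
#' @param table a [CoefficientTable-class] with K >= 3.
#' @return A [NoiseSummary-class].
#' @export
setMethod("cumulants", "CoefficientTable", function(table) {
  k <- .tableKappas(table, 1)
  new("NoiseSummary", mean = unname(k["k1"]), variance = unname(k["k2"]),
      kappa3 = unname(k["k3"]), cv2 = unname(k["k2"] / k["k1"]^2),
      skewness = unname(k["k3"] / k["k2"]^1.5))
})

#' Borel-regularized sum of a term sequence
#'
#' Evaluates `sum_k t_k` as the integral `int_0^inf e^{-t} B(t) dt` with
#' `B(t) = sum_k t_k t^k / k!`, which agrees with the direct sum whenever the
#' latter converges and extends it to alternating divergent sequences whose
#' Borel transform is integrable.
#'
#' @param terms numeric vector of terms (k = 0, 1, ...), or a vector of
#'   signs if `loge` is given.
#' @param loge optional natural-log magnitudes accompanying the signs in
#'   `terms`, for sequences whose terms overflow doubles.
#' @return The regularized sum.
#' @examples
#' borelSum(0.5^(0:60))  # geometric: 2
#' @export
borelSum <- function(terms, loge = NULL) {
  if (is.null(loge)) {
    sgn <- as.integer(sign(terms))
    loge <- ifelse(terms == 0, -Inf, log(abs(terms)))
  } else {
    sgn <- as.integer(terms)
  }
  res <- cpp_borel_sum(sgn, loge)
  if (!res$converged)
    stop("Borel integration could not be carried far enough; the truncated ",
         "inner sum becomes unreliable before the e^(-t) tail is negligible")
  res$value
}

#' Write a PMF as TSV with a JSON metadata sidecar
#'
#' @param pmf a [PMFResult-class].
#' @param path output TSV path; `<path>.json` receives the metadata.
#' @return `path`, invisibly.
#' @export
writePmf <- function(pmf, path) {
  write.table(data.frame(count = pmf@support,
                         probability = pmf@probabilities),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(state = pmf@state, age = pmf@age, method = pmf@method,
               K = pmf@convergence$K,
               normalization_deficit = pmf@convergence$normDeficit,
               clipped_negatives = pmf@convergence$nClipped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Mean and variance of a PMFResult
#' @param pmf a [PMFResult-class].
#' @return Named vector with mean and variance of the (renormalized) PMF.
#' @export
pmfMoments <- function(pmf) {
  p <- pmf@probabilities / sum(pmf@probabilities)
  m <- sum(pmf@support * p)
  c(mean = m, variance = sum((pmf@support - m)^2 * p))
}
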