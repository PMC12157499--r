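# Exact recursions for the derivatives F+^(k)(1) of the birth-state
# generating function, for mRNA and bursty protein.  The heavy lifting runs
# in quadruple precision in C++; the R-side table stores signed natural-log
# magnitudes plus everything needed to re-run the pipeline at full precision.

.newTable <- function(species, raw, K, params, model, age = NA_real_) {
  new("CoefficientTable", species = species, K = as.integer(K),
      sign = raw$sign, loge = raw$loge, params = params, model = model,
      age = age, precision = 33)
}

#' Kinetic parameter constructor
#'
#' @param km transcription (mRNA) or burst-arrival (protein) rate, 1/min.
#' @param gammaM mRNA decay rate, 1/min (mRNA computations).
#' @param b mean geometric burst size (protein computations).
#' @param gammaP protein decay rate, 1/min (protein computations).
#' @return A [GeneParams-class] object.
#' @examples
#' geneParams(km = 0.5, gammaM = 0.05)                  # mRNA
#' geneParams(km = 0.5, b = 2, gammaP = 0.01)           # protein, a = 50
#' @export
geneParams <- function(km, gammaM = NA_real_, b = NA_real_,
                       gammaP = NA_real_) {
  new("GeneParams", km = as.numeric(km), gammaM = as.numeric(gammaM),
      b = as.numeric(b), gammaP = as.numeric(gammaP))
}

#' Dimensionless mean-setting ratio a = km / gammaP
#' @param params a [GeneParams-class].
#' @return a = km / gammaP.
#' @export
aRatio <- function(params) params@km / params@gammaP

.checkMrna <- function(params) {
  if (is.na(params@gammaM)) stop("mRNA computations need gammaM")
}
.checkProtein <- function(params) {
  if (is.na(params@b) || is.na(params@gammaP))
    stop("protein computations need b and gammaP")
}

#' Birth-state coefficient table for mRNA
#'
#' Solves the exact recursion
#' `F_k = 2^{-k} sum_{j<=k} C(k,j) (km/gammaM)^{k-j} Psi[k,j] F_j`
#' for the derivatives of the birth-state generating function at q = 1; the
#' j = k term contains the unknown and is moved to the left-hand side, so
#' each order is solved by a single linear step (no fixed-point iteration).
#'
#' @param params a [GeneParams-class] with `km` and `gammaM`.
#' @param model a [DivisionTimeModel-class].
#' @param K truncation order (coefficients 0..K are computed).
#' @param precision requested working precision in decimal digits; the
#'   backend computes in 113-bit quadruple precision (~33 digits), which is
#'   the maximum supported.
#' @return A [CoefficientTable-class].
#' @examples
#' tab <- mrnaCoefficients(geneParams(0.5, gammaM = 0.05), deltaModel(20), K = 10)
#' coefValues(tab)[2]  # mean at birth, d = 3.8732
#' @export
mrnaCoefficients <- function(params, model, K = 200L, precision = 33) {
  .checkMrna(params)
  .checkPrecision(precision)
  if (K < 0) stop("K must be >= 0")
  raw <- cpp_mrna_table(.familyCode(model), .familyParams(model), params@km,
                        params@gammaM, as.integer(K), tab = .modelTab(model))
  .newTable("mrna", raw, K, params, model)
}

#' Birth-state coefficient table for bursty protein
#'
#' Solves the exact double-sum recursion over Laplace-transform values
#' `L_s = L(s * gammaP)` for the derivatives of the protein birth-state
#' generating function at q = 1. The factorial ratios in the recursion are
#' evaluated as log-gamma differences so that non-integer `a = km/gammaP`
#' is handled smoothly, with the reciprocal-gamma convention (terms with
#' `l > a` vanish for integer `a`).
#'
#' @inheritParams mrnaCoefficients
#' @param params a [GeneParams-class] with `km`, `b` and `gammaP`.
#' @return A [CoefficientTable-class].
#' @export
proteinCoefficients <- function(params, model, K = 250L, precision = 33) {
  .checkProtein(params)
  .checkPrecision(precision)
  if (K < 0) stop("K must be >= 0")
  raw <- cpp_protein_table(.familyCode(model), .familyParams(model),
                           aRatio(params), params@b, params@gammaP,
                           as.integer(K), tab = .modelTab(model))
  .newTable("protein", raw, K, params, model)
}

.checkPrecision <- function(precision) {
  if (precision > 33)
    stop("the numeric backend works in 113-bit quadruple precision ",
         "(~33 decimal digits); precision > 33 is not available. For ",
         "distributions whose series need more headroom, reduce the ",
         "requested support or rely on the Borel-summation fallback.")
}

#' Coefficient values of a table
#'
#' Returns `F^(k)(1)` (or the age-tau coefficients `G^(k)(tau)`) as doubles;
#' values beyond the double range overflow to `Inf`, in which case use
#' [logCoefficients()].
#' @param table a [CoefficientTable-class].
#' @return Numeric vector of length K + 1.
#' @export
coefValues <- function(table) table@sign * exp(table@loge)

#' @rdname coefValues
#' @return For `logCoefficients`, a list with the signs and natural-log
#'   magnitudes.
#' @export
logCoefficients <- function(table) list(sign = table@sign, loge = table@loge)

#' Poisson means of the fixed-division-time mRNA distributions
#'
#' For a fixed division time T the cyclo-stationary mRNA distributions are
#' exactly Poisson with mean `d = (km/gammaM) (1 - exp(-gammaM T)) /
#' (2 - exp(-gammaM T))` at birth and `2 d` just before division.
#'
#' @param params a [GeneParams-class] with `km`, `gammaM`.
#' @param T fixed division time (minutes).
#' @return Named vector `c(d_plus = d, d_minus = 2 d)`.
#' @export
fixedTMrnaClosedForm <- function(params, T) {
  .checkMrna(params)
  if (T <= 0) stop("T must be > 0")
  E <- exp(-params@gammaM * T)
  d <- (params@km / params@gammaM) * (1 - E) / (2 - E)
  c(d_plus = d, d_minus = 2 * d)
}

#' Serialize / restore a coefficient table
#'
#' Writes the signed-log coefficient values and full metadata as JSON, keyed
#' by species, kinetic parameters, division-time model, K and precision, so
#' cached tables can be reloaded without recomputation.
#'
#' @param table a [CoefficientTable-class].
#' @param path file path for the JSON cache.
#' @return `writeCoefficientTable` returns `path` invisibly;
#'   `readCoefficientTable` returns the restored table.
#' @export
writeCoefficientTable <- function(table, path) {
  obj <- list(species = table@species, K = table@K, sign = table@sign,
              log10mag = table@loge / log(10), age = table@age,
              precision = table@precision,
              params = list(km = table@params@km, gamma_m = table@params@gammaM,
                            b = table@params@b, gamma_p = table@params@gammaP),
              model = list(family = table@model@family,
                           params = as.list(table@model@params)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeCoefficientTable
#' @export
readCoefficientTable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$model$family == "custom")
    stop("custom-model tables cannot be restored from JSON")
  model <- do.call(divisionTimeModel,
                   c(list(family = obj$model$family), obj$model$params))
  params <- geneParams(obj$params$km,
                       gammaM = if (is.null(obj$params$gamma_m)) NA_real_
                                else obj$params$gamma_m,
                       b = if (is.null(obj$params$b)) NA_real_ else obj$params$b,
                       gammaP = if (is.null(obj$params$gamma_p)) NA_real_
                                else obj$params$gamma_p)
  new("CoefficientTable", species = obj$species, K = as.integer(obj$K),
      sign = as.integer(obj$sign), loge = obj$log10mag * log(10),
      params = params, model = model,
      age = if (is.null(obj$age)) NA_real_ else obj$age,
      precision = obj$precision)
}
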