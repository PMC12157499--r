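# Closed-form CV^2 formulas for mRNA and protein at cell birth, the additive
# BP/DT/GE decomposition of the protein noise, and the large-mean-division-
# time limits of CV^2 and skewness.  All closed forms are independent of the
# generic coefficient recursion and are cross-checked against it in the
# test-suite.

#' Closed-form CV^2 of the mRNA count at birth
#'
#' Built from the first two coefficients expressed through the Psi
#' integrals: `F1 = c Psi[1,0] / (2 - Psi[1,1])`,
#' `F2 = (c^2 Psi[2,0] + 2 c Psi[2,1] F1) / (4 - Psi[2,2])` with
#' `c = km/gammaM`, giving `CV^2 = (F1 + F2)/F1^2 - 1`. For large mean
#' division times this approaches `2 gammaM / km` for every division-time
#' law.
#'
#' @param params a [GeneParams-class] with `km`, `gammaM`.
#' @param model a [DivisionTimeModel-class].
#' @return The squared coefficient of variation at birth.
#' @export
mrnaCV2 <- function(params, model) {
  .checkMrna(params)
  c0 <- params@km / params@gammaM
  P <- cpp_psi(.familyCode(model), .familyParams(model), params@gammaM, 2L,
               tab = .modelTab(model))
  F1 <- c0 * P[2, 1] / (2 - P[2, 2])
  F2 <- (c0^2 * P[3, 1] + 2 * c0 * P[3, 2] * F1) / (4 - P[3, 3])
  (F1 + F2) / F1^2 - 1
}

# birth-state protein coefficients F1, F2 in closed form from L1, L2
.proteinF12 <- function(a, b, L1, L2) {
  F1 <- a * b * (1 - L1) / (2 - L1)
  F2 <- (a / 2) * (b^2 * ((a + 1) / 2 - a * L1 + (a - 1) * L2 / 2) +
                     b * F1 * (L1 - L2)) / (1 - L2 / 4)
  c(F1 = F1, F2 = F2)
}

#' Closed-form total CV^2 of the protein count at birth
#'
#' Depends on the division-time law only through the Laplace values
#' `L1 = L(gammaP)` and `L2 = L(2 gammaP)`. In the limit of all `L -> 0`
#' (long cycles) it approaches `(b + 2)/(a b)`.
#'
#' @param params a [GeneParams-class] with `km`, `b`, `gammaP`.
#' @param model a [DivisionTimeModel-class].
#' @return The squared coefficient of variation at birth.
#' @examples
#' p <- geneParams(0.5, b = 2, gammaP = 0.01)
#' proteinCV2(p, erlangModel(3, 0.15))  # 0.229
#' @export
proteinCV2 <- function(params, model) {
  .checkProtein(params)
  L <- dtLaplace(model, c(1, 2) * params@gammaP)
  f <- .proteinF12(aRatio(params), params@b, L[1], L[2])
  (f[["F1"]] + f[["F2"]]) / f[["F1"]]^2 - 1
}

#' Additive decomposition of the protein noise at birth
#'
#' Splits the total CV^2 into the binomial-partitioning component
#' `CV2_BP = 2 (2 - L1) / (a b (4 - L2) (1 - L1))`, the purely extrinsic
#' division-time component `CV2_DT` (zero for fixed division times, where
#' `L2 = L1^2`), and the gene-expression component `CV2_GE`; the three are
#' additive. `CV2_GE` is computed both from its closed form and as
#' `total - BP - DT`; a mismatch beyond `1e-6` raises an
#' internal-consistency error.
#'
#' @inheritParams proteinCV2
#' @return A [DecompositionResult-class].
#' @examples
#' p <- geneParams(0.5, b = 2, gammaP = 0.01)
#' decomposeProteinNoise(p, exponentialModel(20))  # DT share ~58%
#' @export
decomposeProteinNoise <- function(params, model) {
  .checkProtein(params)
  a <- aRatio(params); b <- params@b
  L <- dtLaplace(model, c(1, 2) * params@gammaP)
  L1 <- L[1]; L2 <- L[2]
  total <- proteinCV2(params, model)
  bp <- 2 * (2 - L1) / (a * b * (4 - L2) * (1 - L1))
  dt <- -1 + (2 - L1) / ((4 - L2) * (1 - L1)) *
    ((2 - L1) / (1 - L1) * (1 - 2 * L1 + L2) + 2 * (L1 - L2))
  ge <- (2 - L1) * (2 - L2) / (a * b * (1 - L1) * (4 - L2)) +
    (2 - L1)^2 * (1 - L2) / (a * (1 - L1)^2 * (4 - L2))
  if (abs(total - bp - dt - ge) > 1e-6)
    stop("internal inconsistency: closed-form GE component and the ",
         "subtraction route disagree by ", signif(total - bp - dt - ge, 3))
  ge <- total - bp - dt
  new("DecompositionResult", cv2Total = total, cv2BP = bp, cv2DT = dt,
      cv2GE = ge, shares = 100 * c(BP = bp, DT = dt, GE = ge) / total)
}

#' Large-division-time limits of the skewness at birth
#'
#' Obtained by taking `Psi[k,j] -> delta_{j,0}` (mRNA) or `L_s -> 0`
#' (protein) in the coefficient recursion -- the limiting birth-state
#' distributions are Poisson with mean `km/(2 gammaM)` and negative binomial
#' with burst mean `b/2` -- and running the limiting coefficients through
#' the cumulant formulas.
#'
#' @param params a [GeneParams-class].
#' @param species `"mrna"` or `"protein"`.
#' @return The limiting skewness (`sqrt(2 gammaM/km)` for mRNA,
#'   `2 (1 + b) / sqrt(a b (2 + b))` for protein).
#' @export
skewnessLimits <- function(params, species = c("mrna", "protein")) {
  species <- match.arg(species)
  if (species == "mrna") {
    .checkMrna(params)
    cc <- params@km / (2 * params@gammaM)
    k <- .kappas(cc, cc^2, cc^3)
  } else {
    .checkProtein(params)
    a <- aRatio(params); h <- params@b / 2
    k <- .kappas(a * h, a * (a + 1) * h^2, a * (a + 1) * (a + 2) * h^3)
  }
  unname(k["k3"] / k["k2"]^1.5)
}

#' @rdname skewnessLimits
#' @return For `cv2Limits`, the limiting CV^2 (`2 gammaM/km` for mRNA,
#'   `(b + 2)/(a b)` for protein), computed the same way.
#' @export
cv2Limits <- function(params, species = c("mrna", "protein")) {
  species <- match.arg(species)
  if (species == "mrna") {
    .checkMrna(params)
    cc <- params@km / (2 * params@gammaM)
    k <- .kappas(cc, cc^2, cc^3)
  } else {
    .checkProtein(params)
    a <- aRatio(params); h <- params@b / 2
    k <- .kappas(a * h, a * (a + 1) * h^2, a * (a + 1) * (a + 2) * h^3)
  }
  unname(k["k2"] / k["k1"]^2)
}

#' Table of noise decompositions across division-time models
#'
#' @param params a [GeneParams-class] for protein.
#' @param models named list of [DivisionTimeModel-class] objects.
#' @return A data.frame with one row per model: total CV^2, the BP/DT/GE
#'   components, and their percentage shares.
#' @export
decompositionTable <- function(params, models) {
  rows <- lapply(names(models), function(nm) {
    d <- decomposeProteinNoise(params, models[[nm]])
    data.frame(model = nm, cv2 = d@cv2Total, cv2_bp = d@cv2BP,
               cv2_dt = d@cv2DT, cv2_ge = d@cv2GE,
               share_bp = d@shares[["BP"]], share_dt = d@shares[["DT"]],
               share_ge = d@shares[["GE"]])
  })
  do.call(rbind, rows)
}
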