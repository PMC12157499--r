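# Kinetic Monte Carlo validation oracle: exact SSA within each cycle,
# binomial partitioning at division, random (optionally correlated)
# division times, single followed daughter per division.

#' Simulation configuration
#'
#' @param species `"mrna"` or `"protein"`.
#' @param params a [GeneParams-class].
#' @param model a [DivisionTimeModel-class].
#' @param nHistories number of independent lineages.
#' @param burnInCycles cycles discarded before recording (default 100; the
#'   initial condition is forgotten geometrically through the halving at
#'   each division).
#' @param recordCycles recorded cycles per history (default 1).
#' @param ages cell ages (minutes) at which to record age snapshots; a cycle
#'   contributes an age-tau sample only if its duration exceeds tau.
#' @param eps correlation parameter of successive division times, in
#'   \[0, 1): `ts_i = (1 - eps) * draw + eps * ts_{i-1}`.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(species, params, model, nHistories, burnInCycles = 100L,
                      recordCycles = 1L, ages = numeric(0), eps = 0) {
  new("SimConfig", species = species, params = params, model = model,
      nHistories = as.integer(nHistories),
      burnInCycles = as.integer(burnInCycles),
      recordCycles = as.integer(recordCycles),
      ages = sort(as.numeric(ages)), eps = as.numeric(eps))
}

.histFromSamples <- function(x, state, age = NA_real_) {
  x <- x[!is.na(x)]
  tb <- table(factor(x, levels = 0:max(x, 0)))
  new("CountHistogram", counts = setNames(as.integer(tb), names(tb)),
      nSamples = length(x), state = state, age = age)
}

#' Run a lineage simulation
#'
#' Simulates `nHistories` independent single-cell lineages with exact
#' (direct-method) SSA inside each cycle -- mRNA birth/death, or bursty
#' protein production with geometric burst sizes of mean `b` and linear
#' decay -- dividing after each random cycle time by a Binomial(y, 1/2) draw
#' whose result is the followed daughter. After the burn-in, the birth and
#' pre-division counts (and any requested age snapshots) are recorded once
#' per cycle.
#'
#' @param config a [SimConfig-class].
#' @param ... unused.
#' @return A list with [CountHistogram-class] objects `birth`,
#'   `preDivision`, a list `age` (one histogram per requested age), and the
#'   raw sample vectors in `samples`.
#' @examples
#' set.seed(1)
#' cfg <- simConfig("mrna", geneParams(0.5, gammaM = 0.05), deltaModel(20),
#'                  nHistories = 200, burnInCycles = 20)
#' sim <- simulateLineage(cfg)
#' mean(sim$samples$birth)  # ~ 3.87
#' @export
setMethod("simulateLineage", "SimConfig", function(config, ...) {
  sp <- config@species
  p <- config@params
  if (sp == "mrna") .checkMrna(p) else .checkProtein(p)
  model <- config@model
  grid <- if (model@family %in% c("fluctuating_threshold", "custom"))
    .samplerGrid(model) else NULL
  res <- cpp_simulate(if (sp == "mrna") 1L else 2L, .familyCode(model),
                      .familyParams(model), p@km,
                      if (is.na(p@gammaM)) 0 else p@gammaM,
                      if (is.na(p@b)) 0 else p@b,
                      if (is.na(p@gammaP)) 0 else p@gammaP,
                      config@nHistories, config@burnInCycles,
                      config@recordCycles, config@eps, config@ages,
                      grid = grid)
  ages <- lapply(seq_along(config@ages), function(i)
    .histFromSamples(res$age[[i]], "age", config@ages[i]))
  list(birth = .histFromSamples(res$birth, "birth"),
       preDivision = .histFromSamples(res$pre_division, "pre_division"),
       age = ages,
       samples = list(birth = res$birth, preDivision = res$pre_division,
                      age = res$age))
})

#' Simulate single cycles from a fixed initial count
#'
#' Runs the exact within-cycle SSA from `y0` for a duration `ts`, `n` times,
#' returning the endpoint counts and copy numbers at any requested
#' intermediate ages.
#'
#' @param species `"mrna"` or `"protein"`.
#' @param params a [GeneParams-class].
#' @param y0 initial copy number.
#' @param ts cycle duration (minutes).
#' @param ages intermediate ages to snapshot.
#' @param n number of independent replicate cycles.
#' @return List with `endpoint` (integer vector) and `ageSnapshots`
#'   (matrix n x length(ages)).
#' @export
simulateCycle <- function(species, params, y0, ts, ages = numeric(0), n = 1L) {
  if (ts <= 0) stop("ts must be > 0")
  sp <- if (species == "mrna") 1L else 2L
  if (sp == 1L) .checkMrna(params) else .checkProtein(params)
  res <- cpp_simulate_cycle(sp, as.integer(y0), ts, params@km,
                            if (is.na(params@gammaM)) 0 else params@gammaM,
                            if (is.na(params@b)) 0 else params@b,
                            if (is.na(params@gammaP)) 0 else params@gammaP,
                            sort(as.numeric(ages)), as.integer(n))
  list(endpoint = res$endpoint, ageSnapshots = res$age_snapshots)
}

#' Binomial partitioning at division
#'
#' Each of `y` molecules goes independently to either daughter with
#' probability 1/2; the returned draw is the followed daughter's count.
#'
#' @param y non-negative integer count(s) just before division.
#' @return Binomial(y, 1/2) draw(s).
#' @export
binomialPartition <- function(y) {
  if (any(y < 0)) stop("y must be >= 0")
  rbinom(length(y), y, 0.5)
}

#' Empirical probabilities of a count histogram
#' @param hist a [CountHistogram-class].
#' @return Named numeric vector of relative frequencies.
#' @export
histProbabilities <- function(hist) hist@counts / hist@nSamples

#' Total-variation distance between a histogram and an analytic PMF
#'
#' @param hist a [CountHistogram-class].
#' @param pmf a [PMFResult-class] (or a plain numeric vector of
#'   probabilities for counts 0, 1, ...).
#' @return Total-variation distance in \[0, 1\].
#' @export
totalVariation <- function(hist, pmf) {
  p <- if (is(pmf, "PMFResult")) pmf@probabilities else as.numeric(pmf)
  q <- histProbabilities(hist)
  n <- max(length(p), length(q))
  pp <- c(p, rep(0, n - length(p)))
  qq <- c(q, rep(0, n - length(q)))
  sum(abs(pp - qq)) / 2
}
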