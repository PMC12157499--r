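test_that("binomial partitioning has the exact moments", {
  set.seed(1)
  expect_equal(binomialPartition(0L), 0L)
  draws <- binomialPartition(rep(1e6L, 2000))
  expect_equal(mean(draws), 5e5, tolerance = 1e-3)
  expect_equal(var(draws), 1e6 / 4, tolerance = 0.1)
})

test_that("within-cycle kinetics follow the birth-death mean and bursts", {
  set.seed(2)
  pm <- mrnaPars()
  # pure death: km = 0, long cycle empties the cell
  dead <- simulateCycle("mrna", geneParams(0, gammaM = 0.5), y0 = 5,
                        ts = 100, n = 200)
  expect_true(all(dead$endpoint == 0))
  # mean of the linear birth-death process: (km/gm)(1 - exp(-gm t))
  cyc <- simulateCycle("mrna", pm, y0 = 0, ts = 20, ages = c(5, 10), n = 4000)
  for (j in 1:2) {
    t <- c(5, 10)[j]
    expect_equal(mean(cyc$ageSnapshots[, j]), 10 * (1 - exp(-0.05 * t)),
                 tolerance = 0.05)
  }
  # geometric burst size has mean b
  pp <- proteinPars()
  burst <- simulateCycle("protein", geneParams(5, b = 2, gammaP = 1e-9),
                         y0 = 0, ts = 100, n = 2000)
  expect_equal(mean(burst$endpoint) / (5 * 100), 2, tolerance = 0.05)
})

test_that("lineage simulation matches the analytic birth statistics", {
  set.seed(3)
  pp <- proteinPars()
  for (nm in c("delta", "erlang", "exponential")) {
    m <- fourModels()[[nm]]
    cfg <- simConfig("protein", pp, m, nHistories = 1500, burnInCycles = 30,
                     recordCycles = 4)
    sim <- simulateLineage(cfg)
    L1 <- dtLaplace(m, 0.01)
    k1 <- 100 * (1 - L1) / (2 - L1)
    ns <- cumulants(proteinCoefficients(pp, m, K = 3))
    se <- sqrt(ns@variance / length(sim$samples$birth)) *
      sqrt(1 + 2 * 0.7)  # correlated consecutive cycles inflate the s.e.
    expect_lt(abs(mean(sim$samples$birth) - k1), 4 * se, label = nm)
    expect_equal(mean(sim$samples$preDivision),
                 2 * mean(sim$samples$birth), tolerance = 0.05, label = nm)
  }
})

test_that("fixed-T mRNA histogram converges to the Poisson law", {
  set.seed(4)
  pm <- mrnaPars()
  cfg <- simConfig("mrna", pm, deltaModel(20), nHistories = 4000,
                   burnInCycles = 30, recordCycles = 5)
  sim <- simulateLineage(cfg)
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  expect_lt(totalVariation(sim$birth, dpois(0:40, d)), 0.015)
  expect_lt(totalVariation(sim$preDivision, dpois(0:60, 2 * d)), 0.015)
})

test_that("age snapshots agree with the age-resolved analytics", {
  set.seed(5)
  pm <- mrnaPars()
  erl <- erlangModel(3, 0.15)
  cfg <- simConfig("mrna", pm, erl, nHistories = 4000, burnInCycles = 25,
                   recordCycles = 5, ages = c(5, 10))
  sim <- simulateLineage(cfg)
  tab <- mrnaCoefficients(pm, erl, K = 200)
  for (j in 1:2) {
    tau <- c(5, 10)[j]
    pmf <- pmfAtAge(tab, tau, ymax = 30)
    expect_lt(totalVariation(sim$age[[j]], pmf), 0.02)
  }
})

test_that("correlated division times keep the mean and gain persistence", {
  set.seed(6)
  erl <- erlangModel(3, 0.15)
  ts0 <- nextDivisionTimes(erl, 3e4, eps = 0)
  ts5 <- nextDivisionTimes(erl, 3e4, eps = 0.5)
  ts9 <- nextDivisionTimes(erl, 3e4, eps = 0.95)
  expect_equal(mean(ts5), 20, tolerance = 0.02)
  expect_equal(mean(ts9), 20, tolerance = 0.05)
  acf1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(acf1(ts0)), 0.02)
  expect_equal(acf1(ts5), 0.5, tolerance = 0.05)
  expect_gt(acf1(ts9), 0.9)
})

test_that("correlation-induced deviations are larger for protein than mRNA", {
  set.seed(8)
  pm <- mrnaPars()
  pp <- proteinPars()
  erl <- erlangModel(3, 0.15)
  n <- 2500; rec <- 8
  tvFor <- function(species, pars, tab) {
    cfg <- simConfig(species, pars, erl, nHistories = n, burnInCycles = 25,
                     recordCycles = rec, eps = 0.5)
    sim <- simulateLineage(cfg)
    totalVariation(sim$birth, pmfAtBirth(tab))
  }
  tvM <- tvFor("mrna", pm, mrnaCoefficients(pm, erl, K = 200))
  tvP <- tvFor("protein", pp, proteinCoefficients(pp, erl, K = 300))
  expect_gt(tvP, tvM)
})
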