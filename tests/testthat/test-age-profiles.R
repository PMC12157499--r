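test_that("age transform at tau = 0 is the identity", {
  pm <- mrnaPars()
  tab <- mrnaCoefficients(pm, erlangModel(3, 0.15), K = 60)
  a0 <- ageCoefficients(tab, 0)
  expect_equal(coefValues(a0), coefValues(tab), tolerance = 1e-12)
  pp <- proteinPars()
  tabP <- proteinCoefficients(pp, erlangModel(3, 0.15), K = 40)
  a0P <- ageCoefficients(tabP, 0)
  expect_equal(logCoefficients(a0P)$loge, logCoefficients(tabP)$loge,
               tolerance = 1e-10)
  # order zero is 1 for all tau (normalization)
  a7 <- ageCoefficients(tab, 7)
  expect_equal(coefValues(a7)[1], 1)
})

test_that("mRNA age coefficients approach the within-cycle limit", {
  pm <- mrnaPars()
  tab <- mrnaCoefficients(pm, erlangModel(3, 0.15), K = 10)
  aInf <- ageCoefficients(tab, 1e4)
  expect_equal(coefValues(aInf), 10^(0:10), tolerance = 1e-8)
})

test_that("age-tau PMFs: birth identity, delta Poisson law, normalization", {
  pm <- mrnaPars()
  tab <- mrnaCoefficients(pm, erlangModel(3, 0.15), K = 200)
  p0 <- pmfAtAge(tab, 0, ymax = 25)
  b0 <- pmfAtBirth(tab, ymax = 25)
  expect_equal(p0@probabilities, b0@probabilities, tolerance = 1e-10)
  # fixed-T model at age tau: Poisson with mean d e^(-g tau) + (km/g)(1 - e^(-g tau))
  tabD <- mrnaCoefficients(pm, deltaModel(20), K = 120)
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  for (tau in c(2, 5, 12)) {
    mu <- d * exp(-0.05 * tau) + 10 * (1 - exp(-0.05 * tau))
    pt <- pmfAtAge(tabD, tau, ymax = 30)
    expect_equal(pt@probabilities, dpois(0:30, mu), tolerance = 1e-10)
  }
  for (tau in c(0, 3, 9, 25))
    expect_lt(abs(1 - sum(pmfAtAge(tab, tau)@probabilities)), 1e-4)
})

test_that("age-averaged PMF sits between birth and pre-division", {
  pm <- mrnaPars()
  erl <- erlangModel(3, 0.15)
  tab <- mrnaCoefficients(pm, erl, K = 200)
  w <- powellAgeWeight(erl)
  avg <- ageAveragedPmf(tab, w)
  expect_lt(abs(1 - sum(avg@probabilities)), 2e-4)
  mb <- cumulants(tab)@mean
  mavg <- pmfMoments(avg)[["mean"]]
  expect_gt(mavg, mb)
  expect_lt(mavg, 2 * mb)
})

test_that("delta-model age average reduces to the fixed-T age density", {
  pm <- mrnaPars()
  dm <- deltaModel(20)
  tab <- mrnaCoefficients(pm, dm, K = 150)
  w <- powellAgeWeight(dm)
  # phi(tau) = (ln 2 / T) 2^(1 - tau/T) on [0, T]
  tt <- c(1, 7, 19)
  expect_equal(ageDensity(w, tt), log(2) / 20 * 2^(1 - tt / 20),
               tolerance = 1e-10)
  avg <- ageAveragedPmf(tab, w, ymax = 30)
  # direct integral oracle: Poisson mean mu(tau) averaged over phi
  oracle <- vapply(0:30, function(y) {
    integrate(function(tau) {
      mu <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]] * exp(-0.05 * tau) +
        10 * (1 - exp(-0.05 * tau))
      ageDensity(w, tau) * dpois(y, mu)
    }, 0, 20, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(avg@probabilities, oracle, tolerance = 1e-6)
})

test_that("protein age-averaged PMF normalizes", {
  pp <- proteinPars()
  erl <- erlangModel(3, 0.15)
  tab <- proteinCoefficients(pp, erl, K = 300)
  avg <- ageAveragedPmf(tab, powellAgeWeight(erl), nNodes = 48L)
  expect_lt(abs(1 - sum(avg@probabilities)), 2e-4)
  m <- pmfMoments(avg)[["mean"]]
  expect_gt(m, cumulants(tab)@mean)
  expect_lt(m, 2 * cumulants(tab)@mean)
})
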