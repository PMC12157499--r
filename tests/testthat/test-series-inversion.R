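test_that("fixed-T mRNA inverts to exact Poisson at birth and pre-division", {
  pm <- mrnaPars()
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  tab <- mrnaCoefficients(pm, deltaModel(20), K = 80)
  birth <- pmfAtBirth(tab, ymax = 25)
  expect_equal(birth@probabilities, dpois(0:25, d), tolerance = 1e-10)
  pre <- pmfBeforeDivision(tab, ymax = 40)
  expect_equal(pre@probabilities, dpois(0:40, 2 * d), tolerance = 1e-10)
})

test_that("generic pipeline equals the exponential-model closed form", {
  pm <- mrnaPars()
  tab <- mrnaCoefficients(pm, exponentialModel(20), K = 250)
  birth <- pmfAtBirth(tab, ymax = 20)
  expect_equal(birth@probabilities, eq23ClosedForm(0:20, 0.25, 20, 0.05),
               tolerance = 1e-8)
  # the pre-division oracle is evaluated in doubles and its alternating
  # terms reach ~e^13, so the reference itself carries ~1e-8 relative noise
  pre <- pmfBeforeDivision(tab, ymax = 30)
  expect_equal(pre@probabilities, eq23ClosedForm(0:30, 0.5, 20, 0.05),
               tolerance = 1e-6)
})

test_that("PMFs normalize and reproduce the exact cumulants", {
  pm <- mrnaPars()
  pp <- proteinPars()
  for (nm in c("delta", "erlang", "exponential")) {
    m <- fourModels()[[nm]]
    tab <- mrnaCoefficients(pm, m, K = 200)
    pmf <- pmfAtBirth(tab)
    expect_lt(abs(1 - sum(pmf@probabilities)), 1e-4)
    ns <- cumulants(tab)
    mo <- pmfMoments(pmf)
    expect_equal(mo[["mean"]], ns@mean, tolerance = 1e-4, label = nm)
    expect_equal(mo[["variance"]], ns@variance, tolerance = 1e-3, label = nm)
  }
  tabP <- proteinCoefficients(pp, fourModels()$erlang, K = 400)
  pmfP <- pmfAtBirth(tabP)
  expect_lt(abs(1 - sum(pmfP@probabilities)), 1e-4)
  nsP <- cumulants(tabP)
  expect_equal(pmfMoments(pmfP)[["mean"]], nsP@mean, tolerance = 1e-4)
  expect_equal(pmfMoments(pmfP)[["variance"]], nsP@variance, tolerance = 1e-3)
})

test_that("protein birth PMF matches the fixed-T product-form oracle", {
  pp <- proteinPars()
  tab <- proteinCoefficients(pp, deltaModel(20), K = 400)
  pmf <- pmfAtBirth(tab, ymax = 60)
  oracle <- deltaProteinSeries(0, 60, a = 50, b = 2, gp = 0.01, T = 20)
  expect_equal(pmf@probabilities, oracle, tolerance = 1e-8)
})

test_that("pre-division mean is twice the birth mean for every model", {
  pm <- mrnaPars()
  for (nm in names(fourModels())) {
    tab <- mrnaCoefficients(pm, fourModels()[[nm]], K = 250)
    b <- pmfMoments(pmfAtBirth(tab))
    p <- pmfMoments(pmfBeforeDivision(tab))
    expect_equal(p[["mean"]], 2 * b[["mean"]], tolerance = 1e-3, label = nm)
  }
})

test_that("cumulants follow the exact first-three-coefficient formulas", {
  pm <- mrnaPars()
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  ns <- cumulants(mrnaCoefficients(pm, deltaModel(20), K = 3))
  expect_equal(c(ns@mean, ns@variance, ns@kappa3), rep(d, 3),
               tolerance = 1e-12)
  expect_equal(ns@skewness, 1 / sqrt(d), tolerance = 1e-12)
  expect_error(cumulants(mrnaCoefficients(pm, deltaModel(20), K = 2)),
               "K >= 3")
})

test_that("CV^2 decreases monotonically with the mean division time", {
  pm <- mrnaPars()
  means <- 10 * 2^(0:6)
  for (fam in c("delta", "erlang", "exponential")) {
    cv2 <- vapply(means, function(Tm) {
      m <- switch(fam, delta = deltaModel(Tm),
                  erlang = erlangModel(3, 3 / Tm),
                  exponential = exponentialModel(Tm))
      mrnaCV2(pm, m)
    }, numeric(1))
    expect_true(all(diff(cv2) < 0), label = fam)
  }
})

test_that("Borel summation reproduces its reference sums", {
  expect_equal(borelSum(0.5^(0:100)), 2, tolerance = 1e-10)
  # alternating divergent geometric series, Abel value 1/(1+1.5)
  expect_equal(borelSum((-1.5)^(0:200)), 0.4, tolerance = 1e-8)
  # Eq.-11-type terms for the fixed-T model at y = 0 sum to exp(-d)
  d <- fixedTMrnaClosedForm(mrnaPars(), 20)[["d_plus"]]
  k <- 0:120
  expect_equal(borelSum(as.integer((-1)^k), k * log(d) - lgamma(k + 1)),
               exp(-d), tolerance = 1e-10)
  # exponential-model terms at y = 0 agree with the closed form
  tab <- mrnaCoefficients(mrnaPars(), exponentialModel(20), K = 200)
  lc <- logCoefficients(tab)
  expect_equal(borelSum(as.integer((-1)^(0:200) * lc$sign),
                        lc$loge - lgamma(0:200 + 1)),
               eq23ClosedForm(0, 0.25, 20, 0.05), tolerance = 1e-8)
})

test_that("PMF output files round-trip", {
  tab <- mrnaCoefficients(mrnaPars(), deltaModel(20), K = 60)
  pmf <- pmfAtBirth(tab, ymax = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePmf(pmf, path)
  back <- read.delim(path)
  expect_equal(back$probability, pmf@probabilities, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$state, "birth")
})
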