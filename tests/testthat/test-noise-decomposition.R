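paperTable1 <- data.frame(
  model = c("delta", "beta_exponential", "erlang", "exponential"),
  cv2 = c(0.149, 0.174, 0.229, 0.372),
  bp = c(0.039, 0.039, 0.040, 0.042),
  dt = c(0, 0.025, 0.078, 0.217),
  ge = c(0.110, 0.110, 0.111, 0.113))

test_that("closed-form CV^2 equals the cumulant pipeline (both species)", {
  pm <- mrnaPars()
  pp <- proteinPars()
  for (nm in names(fourModels())) {
    m <- fourModels()[[nm]]
    nsM <- cumulants(mrnaCoefficients(pm, m, K = 3))
    expect_equal(mrnaCV2(pm, m), nsM@cv2, tolerance = 1e-10, label = nm)
    nsP <- cumulants(proteinCoefficients(pp, m, K = 3))
    expect_equal(proteinCV2(pp, m), nsP@cv2, tolerance = 1e-10, label = nm)
  }
})

test_that("protein noise decomposition reproduces the reference table", {
  pp <- proteinPars()
  for (i in seq_len(4)) {
    m <- fourModels()[[paperTable1$model[i]]]
    d <- decomposeProteinNoise(pp, m)
    got <- c(d@cv2Total, d@cv2BP, d@cv2DT, d@cv2GE)
    ref <- unlist(paperTable1[i, c("cv2", "bp", "dt", "ge")])
    # printed to three decimals: agree to within one unit in the last digit
    expect_lt(max(abs(got - ref)), 1.05e-3, label = paperTable1$model[i])
  }
})

test_that("decomposition is additive and DT vanishes for fixed times", {
  pp <- proteinPars()
  for (nm in names(fourModels())) {
    d <- decomposeProteinNoise(pp, fourModels()[[nm]])
    expect_equal(d@cv2Total, d@cv2BP + d@cv2DT + d@cv2GE, tolerance = 1e-10,
                 label = nm)
    expect_equal(sum(d@shares), 100, tolerance = 1e-8)
  }
  expect_equal(decomposeProteinNoise(pp, deltaModel(20))@cv2DT, 0,
               tolerance = 1e-12)
})

test_that("percentage shares match the reported integers", {
  pp <- proteinPars()
  dE <- decomposeProteinNoise(pp, erlangModel(3, 0.15))
  expect_equal(round(unname(dE@shares)), c(18, 34, 48), tolerance = 1)
  dX <- decomposeProteinNoise(pp, exponentialModel(20))
  expect_equal(round(dX@shares[["DT"]]), 58)
  expect_equal(round(dX@shares[["GE"]]), 30)
})

test_that("noise hierarchy follows division-time variability", {
  pp <- proteinPars()
  cv2 <- vapply(fourModels(), function(m) proteinCV2(pp, m), numeric(1))
  expect_true(all(diff(cv2[c("delta", "beta_exponential", "erlang",
                              "exponential")]) > 0))
})

test_that("large-division-time limits of CV^2 and skewness", {
  pm <- mrnaPars()
  pp <- proteinPars()
  expect_equal(cv2Limits(pm, "mrna"), 0.2, tolerance = 1e-12)
  expect_equal(skewnessLimits(pm, "mrna"), sqrt(0.2), tolerance = 1e-12)
  expect_equal(round(skewnessLimits(pm, "mrna"), 3), 0.447)
  expect_equal(cv2Limits(pp, "protein"), 0.04, tolerance = 1e-12)
  expect_equal(skewnessLimits(pp, "protein"), 0.3, tolerance = 1e-12)
  # the closed forms converge to those limits
  expect_equal(mrnaCV2(pm, deltaModel(5e4)), 0.2, tolerance = 1e-6)
  expect_equal(proteinCV2(pp, deltaModel(5e5)), 0.04, tolerance = 1e-4)
  # Poisson check at finite T
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  ns <- cumulants(mrnaCoefficients(pm, deltaModel(20), K = 3))
  expect_equal(ns@skewness, 1 / sqrt(d), tolerance = 1e-12)
})

test_that("protein skewness is non-monotone in the mean division time", {
  pp <- proteinPars()
  means <- c(20, 50, 100, 200, 400, 800, 1600, 3200)
  sk <- vapply(means, function(Tm)
    cumulants(proteinCoefficients(pp, exponentialModel(Tm), K = 3))@skewness,
    numeric(1))
  imin <- which.min(sk)
  expect_gt(imin, 1)
  expect_lt(imin, length(sk))
})

test_that("decomposition table collects models", {
  tab <- decompositionTable(proteinPars(), fourModels())
  expect_equal(nrow(tab), 4)
  expect_equal(tab$cv2, tab$cv2_bp + tab$cv2_dt + tab$cv2_ge,
               tolerance = 1e-10)
})
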