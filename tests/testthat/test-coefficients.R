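test_that("fixed division times give F_k = d^k (Poisson structure)", {
  pm <- mrnaPars()
  d <- fixedTMrnaClosedForm(pm, 20)[["d_plus"]]
  expect_equal(d, 10 * (1 - exp(-1)) / (2 - exp(-1)), tolerance = 1e-14)
  expect_equal(round(d, 4), 3.873)
  tab <- mrnaCoefficients(pm, deltaModel(20), K = 20)
  expect_equal(coefValues(tab), d^(0:20), tolerance = 1e-12)
})

test_that("fixed-T closed form has the stated limits", {
  pm <- mrnaPars()
  expect_lt(fixedTMrnaClosedForm(pm, 1e-8)[["d_plus"]], 1e-8)
  # T -> Inf: the birth mean is half the within-cycle stationary mean km/gm
  expect_equal(fixedTMrnaClosedForm(pm, 1e6)[["d_plus"]], 5, tolerance = 1e-8)
  expect_equal(fixedTMrnaClosedForm(pm, 20)[["d_minus"]],
               2 * fixedTMrnaClosedForm(pm, 20)[["d_plus"]])
})

test_that("mRNA recursion matches the exponential-model closed form", {
  pm <- mrnaPars()
  tab <- mrnaCoefficients(pm, exponentialModel(20), K = 10)
  k <- 1:10
  closed <- vapply(k, function(kk)
    (0.25)^kk * factorial(kk) /
      prod(1 / 20 + 0.05 * (1:kk) - 2^-(1:kk) / 20), numeric(1))
  expect_equal(coefValues(tab)[-1], closed, tolerance = 1e-10)
})

test_that("trivial and empty-cell cases", {
  pm <- mrnaPars()
  tab0 <- mrnaCoefficients(pm, erlangModel(3, 0.15), K = 0)
  expect_equal(coefValues(tab0), 1)
  silent <- geneParams(0, gammaM = 0.05)
  tabS <- mrnaCoefficients(silent, erlangModel(3, 0.15), K = 8)
  expect_equal(coefValues(tabS), c(1, rep(0, 8)))
})

test_that("protein recursion: mean formula and the delta-model product oracle", {
  pp <- proteinPars()
  for (nm in names(fourModels())) {
    m <- fourModels()[[nm]]
    L1 <- dtLaplace(m, 0.01)
    tab <- proteinCoefficients(pp, m, K = 3)
    expect_equal(coefValues(tab)[2], 100 * (1 - L1) / (2 - L1),
                 tolerance = 1e-10, label = nm)
  }
  # erlang mean 14.969 (from L1 = (0.15/0.16)^3)
  tabE <- proteinCoefficients(pp, erlangModel(3, 0.15), K = 1)
  expect_equal(coefValues(tabE)[2], 14.9678, tolerance = 1e-4)
  # independent infinite-product oracle for fixed division times, k <= 30
  f <- deltaProteinSeries(1, 30, a = 50, b = 2, gp = 0.01, T = 20)
  tabD <- proteinCoefficients(pp, deltaModel(20), K = 30)
  expect_equal(coefValues(tabD) / factorial(0:30), f, tolerance = 1e-11)
})

test_that("protein recursion is continuous across integer a", {
  mk <- function(km) coefValues(
    proteinCoefficients(geneParams(km, b = 2, gammaP = 0.01),
                        erlangModel(3, 0.15), K = 20))
  lo <- mk(0.49999)
  mid <- mk(0.5)
  hi <- mk(0.50001)
  # the change across the integer is the smooth physical a-dependence:
  # the integer-a value is bracketed by its neighbours, with no jump
  expect_true(all(lo <= mid * (1 + 1e-10) & mid <= hi * (1 + 1e-10)))
  expect_equal(lo / mid, hi / mid * (mid / hi)^2, tolerance = 1e-4)
})

test_that("coefficient tables serialize and restore losslessly", {
  pp <- proteinPars()
  tab <- proteinCoefficients(pp, erlangModel(3, 0.15), K = 10)
  path <- withr::local_tempfile(fileext = ".json")
  writeCoefficientTable(tab, path)
  back <- readCoefficientTable(path)
  expect_equal(logCoefficients(back), logCoefficients(tab))
  expect_equal(back@model@family, "erlang")
  expect_equal(back@params@b, 2)
})

test_that("requesting unavailable precision is refused with advice", {
  expect_error(mrnaCoefficients(mrnaPars(), deltaModel(20), K = 5,
                                precision = 200), "precision")
})
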