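test_that("densities match closed forms and integrate to one", {
  expect_equal(dtDensity(exponentialModel(20), 20), exp(-1) / 20,
               tolerance = 1e-12)
  # Erlang with N = 1 coincides with the exponential of the same mean
  expect_equal(dtDensity(erlangModel(1, 0.05), 10),
               dtDensity(exponentialModel(20), 10), tolerance = 1e-12)
  for (nm in c("beta_exponential", "erlang", "exponential")) {
    m <- fourModels()[[nm]]
    mass <- integrate(function(t) dtDensity(m, t), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8, label = nm)
  }
  # the threshold-fluctuation families are normalized on their support
  grh <- growthRateModel(0.035, 0.0052)
  expect_equal(integrate(function(t) dtDensity(grh, t), 1, 400)$value, 1,
               tolerance = 1e-6)
  ft <- fluctuatingThresholdModel(0.035, 0.0052, 0.1)
  expect_equal(integrate(function(t) dtDensity(ft, t), 0.5, 2000)$value, 1,
               tolerance = 1e-5)
  expect_error(dtDensity(deltaModel(20), 10), "analytically")
  expect_error(betaExponentialModel(20, 25, 0.03), "n0")
})

test_that("moments: closed forms and the Fig.-3 calibration", {
  expect_equal(unname(dtMoments(erlangModel(3, 0.15))), c(20, 1 / 3),
               tolerance = 1e-12)
  expect_equal(unname(dtMoments(deltaModel(20))), c(20, 0))
  expect_equal(dtMoments(exponentialModel(20))[["cv2"]], 1)
  be <- calibrateBetaExponential(20, 10, 20)
  expect_equal(be@params[["beta"]], sum(1 / (10:19)) / 20, tolerance = 1e-14)
  expect_equal(dtMoments(be)[["cv2"]], sum(1 / (10:19)^2) / sum(1 / (10:19))^2,
               tolerance = 1e-12)
  expect_equal(round(dtMoments(be)[["cv2"]], 3), 0.104)
  # mean reproduced by quadrature of the density itself
  mq <- integrate(function(t) t * dtDensity(be, t), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(mq, 20, tolerance = 1e-8)
  # the single-stage case collapses to one exponential
  be1 <- calibrateBetaExponential(2, 1, 1)
  expect_equal(be1@params[["beta"]], 1)
})

test_that("Laplace transform: closed forms, quadrature and L(0) = 1", {
  expect_equal(dtLaplace(deltaModel(20), 0), 1)
  expect_equal(dtLaplace(exponentialModel(20), 0.05), 0.5, tolerance = 1e-14)
  expect_equal(dtLaplace(erlangModel(3, 0.15), 0.01), (0.15 / 0.16)^3,
               tolerance = 1e-13)
  for (nm in names(fourModels())) {
    m <- fourModels()[[nm]]
    expect_equal(dtLaplace(m, 0), 1, tolerance = 1e-10, label = nm)
    # cross-check closed forms against direct quadrature of the density
    if (nm != "delta") {
      lq <- integrate(function(t) dtDensity(m, t) * exp(-0.01 * t), 0, Inf,
                      rel.tol = 1e-12)$value
      expect_equal(dtLaplace(m, 0.01), lq, tolerance = 1e-9, label = nm)
    }
  }
  expect_equal(dtLaplace(growthRateModel(0.035, 0.0052), 0), 1,
               tolerance = 1e-6)
})

test_that("Psi integrals: closed forms, expansion identities, quadrature", {
  gm <- 0.05
  # delta closed form exp(-j gm T)(1 - exp(-gm T))^(k-j)
  dm <- deltaModel(20)
  for (kj in list(c(0, 0), c(1, 0), c(3, 2), c(6, 6))) {
    k <- kj[1]; j <- kj[2]
    expect_equal(dtPsi(dm, k, j, gm),
                 exp(-j * gm * 20) * (1 - exp(-gm * 20))^(k - j),
                 tolerance = 1e-13)
  }
  # Psi[k,k] = L(k gamma); Psi[0,0] = 1
  for (nm in names(fourModels())) {
    m <- fourModels()[[nm]]
    expect_equal(dtPsi(m, 0, 0, gm), 1, tolerance = 1e-10, label = nm)
    expect_equal(dtPsi(m, 1, 1, gm), dtLaplace(m, gm), tolerance = 1e-10,
                 label = nm)
  }
  expect_equal(dtPsi(exponentialModel(20), 1, 1, gm), 0.5, tolerance = 1e-12)
  # quadrature values equal the alternating binomial expansion into Laplace
  # values for k <= 10
  for (nm in c("erlang", "exponential", "beta_exponential")) {
    m <- fourModels()[[nm]]
    for (kj in list(c(4, 1), c(7, 3), c(10, 0))) {
      k <- kj[1]; j <- kj[2]
      r <- 0:(k - j)
      psiExp <- sum(choose(k - j, r) * (-1)^r * dtLaplace(m, (j + r) * gm))
      expect_equal(dtPsi(m, k, j, gm), psiExp, tolerance = 1e-8, label = nm)
    }
  }
  expect_error(dtPsi(dm, 2, 3, gm), "j <= k")
})

test_that("Powell age weight: implicit growth rate and normalization", {
  # exponential: 2/(1 + vm T) = 1 => vm = 1/T
  we <- powellAgeWeight(exponentialModel(20))
  expect_equal(we@vm, 1 / 20, tolerance = 1e-10)
  # delta: 2 exp(-vm T) = 1 => vm = ln 2 / T
  wd <- powellAgeWeight(deltaModel(20))
  expect_equal(wd@vm, log(2) / 20, tolerance = 1e-10)
  # erlang: vm = lambda (2^(1/N) - 1)
  wr <- powellAgeWeight(erlangModel(3, 0.15))
  expect_equal(wr@vm, 0.15 * (2^(1 / 3) - 1), tolerance = 1e-10)
  for (w in list(we, wd, wr))
    expect_equal(w@normCheck, 1, tolerance = 1e-6)
})

test_that("sampling reproduces each family's density and moments", {
  set.seed(42)
  expect_equal(dtSample(deltaModel(20), 5), rep(20, 5))
  s <- dtSample(erlangModel(3, 0.15), 4e4)
  expect_equal(mean(s), 20, tolerance = 0.02)
  expect_equal(var(s) / mean(s)^2, 1 / 3, tolerance = 0.05)
  sb <- dtSample(calibrateBetaExponential(20, 10, 20), 4e4)
  expect_equal(mean(sb), 20, tolerance = 0.02)
  expect_equal(var(sb) / mean(sb)^2, 0.104, tolerance = 0.05)
  # KS agreement between the empirical draw and the density via its CDF
  m <- exponentialModel(20)
  se <- dtSample(m, 2e4)
  ks <- suppressWarnings(ks.test(se, function(q) 1 - exp(-q / 20)))
  expect_gt(ks$p.value, 1e-4)
  # inverse-CDF family
  ft <- fluctuatingThresholdModel(0.035, 0.0052, 0.1)
  sf <- dtSample(ft, 3e4)
  expect_equal(mean(sf), dtMoments(ft)[["mean"]], tolerance = 0.03)
  grh <- growthRateModel(0.035, 0.0052)
  sg <- dtSample(grh, 3e4)
  expect_equal(mean(sg), dtMoments(grh)[["mean"]], tolerance = 0.02)
})

test_that("custom models accept a user density", {
  m <- customModel(density = function(t) dgamma(t, shape = 3, rate = 0.15),
                   upper = 400)
  expect_equal(dtMoments(m)[["mean"]], 20, tolerance = 1e-6)
  expect_equal(dtLaplace(m, 0.01), (0.15 / 0.16)^3, tolerance = 1e-8)
  expect_equal(dtPsi(m, 2, 1, 0.05), dtPsi(erlangModel(3, 0.15), 2, 1, 0.05),
               tolerance = 1e-8)
})
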