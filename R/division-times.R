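# Constructors, densities, moments, Laplace transforms, the Psi integrals
# entering the mRNA recursion, the Powell age weight, and sampling, for the
# built-in division-time families.

.familyCode <- function(model) .dtFamilies[[model@family]]

# parameter vector in the order the C++ core expects
.familyParams <- function(model) {
  p <- model@params
  switch(model@family,
    delta = p[["T"]],
    exponential = p[["T"]],
    erlang = c(p[["N"]], p[["lambda"]]),
    beta_exponential = c(p[["X"]], p[["n0"]], p[["beta"]]),
    growth_rate_heterogeneity = c(p[["beta0"]], p[["sigma_beta"]]),
    fluctuating_threshold = c(p[["beta0"]], p[["sigma_beta"]], p[["sigma_X"]]),
    custom = numeric(0))
}

# tabulated quadrature (nodes, weights, density values) for custom models
.customTab <- function(model) {
  gl <- cpp_gl_nodes(32L)
  npan <- 48L
  edges <- seq(0, model@upper, length.out = npan + 1L)
  t <- w <- numeric(0)
  for (i in seq_len(npan)) {
    h <- (edges[i + 1L] - edges[i]) / 2
    t <- c(t, edges[i] + h * (gl$x + 1))
    w <- c(w, h * gl$w)
  }
  g <- vapply(t, model@density, numeric(1))
  if (any(!is.finite(g)) || any(g < 0))
    stop("custom density returned non-finite or negative values")
  list(t = t, w = w, g = g)
}

.modelTab <- function(model) {
  if (model@family == "custom") .customTab(model) else NULL
}

#' Construct a division-time model
#'
#' @param family one of `"delta"`, `"exponential"`, `"erlang"`,
#'   `"beta_exponential"`, `"growth_rate_heterogeneity"`,
#'   `"fluctuating_threshold"`, `"custom"`.
#' @param ... family parameters (see the shortcut constructors).
#' @param density,sampler,upper for `family = "custom"`: the density on
#'   (0, Inf), an optional sampler `function(n)`, and the upper quadrature
#'   truncation point (choose it so the tail mass beyond is negligible).
#'
#' @return A [DivisionTimeModel-class] object.
#' @examples
#' erlangModel(N = 3, lambda = 0.15)     # mean 20 min, CV^2 = 1/3
#' exponentialModel(mean = 20)
#' @export
divisionTimeModel <- function(family, ..., density = NULL, sampler = NULL,
                              upper = NA_real_) {
  params <- unlist(list(...))
  if (length(params)) params <- setNames(as.numeric(params),
                                         names(unlist(list(...))))
  new("DivisionTimeModel", family = family,
      params = if (length(params)) params else numeric(0),
      density = density, sampler = sampler, upper = upper)
}

#' @rdname divisionTimeModel
#' @param T fixed division time, or mean of the exponential law (minutes).
#' @export
deltaModel <- function(T) divisionTimeModel("delta", T = T)

#' @rdname divisionTimeModel
#' @param mean mean division time (minutes).
#' @export
exponentialModel <- function(mean) divisionTimeModel("exponential", T = mean)

#' @rdname divisionTimeModel
#' @param N Erlang shape (number of effective exponential stages).
#' @param lambda Erlang rate (1/min); the mean is N / lambda.
#' @export
erlangModel <- function(N, lambda) divisionTimeModel("erlang", N = N,
                                                     lambda = lambda)

#' @rdname divisionTimeModel
#' @param X threshold copy number of the autocatalytic growth process.
#' @param n0 initial copy number (0 < n0 < X).
#' @param beta per-unit autocatalytic growth rate (1/min).
#' @export
betaExponentialModel <- function(X, n0, beta)
  divisionTimeModel("beta_exponential", X = X, n0 = n0, beta = beta)

#' @rdname divisionTimeModel
#' @param beta0 mean exponential growth rate (1/min).
#' @param sigma_beta s.d. of the growth rate across cells (1/min).
#' @export
growthRateModel <- function(beta0, sigma_beta)
  divisionTimeModel("growth_rate_heterogeneity", beta0 = beta0,
                    sigma_beta = sigma_beta)

#' @rdname divisionTimeModel
#' @param sigma_X s.d. of the Gaussian fluctuation of log(X / n0).
#' @export
fluctuatingThresholdModel <- function(beta0, sigma_beta, sigma_X)
  divisionTimeModel("fluctuating_threshold", beta0 = beta0,
                    sigma_beta = sigma_beta, sigma_X = sigma_X)

#' @rdname divisionTimeModel
#' @export
customModel <- function(density, sampler = NULL, upper)
  divisionTimeModel("custom", density = density, sampler = sampler,
                    upper = upper)

#' Division-time density g(ts)
#'
#' Evaluates the probability density of the cell-cycle duration. The `delta`
#' family has no density function; its moments and transforms are handled
#' analytically, and calling `dtDensity` on it is an error.
#'
#' @param model a [DivisionTimeModel-class].
#' @param ts vector of times (minutes), all > 0.
#' @return Density values g(ts).
#' @export
setMethod("dtDensity", "DivisionTimeModel", function(model, ts) {
  if (any(ts <= 0)) stop("ts must be positive")
  if (model@family == "delta")
    stop("the delta family is handled analytically and has no density ",
         "function; use dtMoments()/dtLaplace() instead")
  if (model@family == "custom") return(vapply(ts, model@density, numeric(1)))
  cpp_density(.familyCode(model), .familyParams(model), ts)
})

#' Mean and squared coefficient of variation of the division time
#'
#' Closed forms are used where available (delta, exponential, Erlang,
#' beta-exponential); otherwise moments are computed by quadrature.
#'
#' @param model a [DivisionTimeModel-class].
#' @return Named numeric vector `c(mean = , cv2 = )`.
#' @export
setMethod("dtMoments", "DivisionTimeModel", function(model) {
  p <- model@params
  switch(model@family,
    delta = c(mean = unname(p[["T"]]), cv2 = 0),
    exponential = c(mean = unname(p[["T"]]), cv2 = 1),
    erlang = c(mean = p[["N"]] / p[["lambda"]], cv2 = 1 / p[["N"]]),
    beta_exponential = {
      s <- p[["n0"]]:(p[["X"]] - 1)
      m <- sum(1 / s) / p[["beta"]]
      v <- sum(1 / s^2) / p[["beta"]]^2
      c(mean = m, cv2 = v / m^2)
    },
    { # quadrature families
      tab <- .quadTab(model)
      m0 <- sum(tab$w * tab$g)
      if (m0 < 0.99)
        stop("density mass on the quadrature domain is only ", signif(m0, 4),
             "; the custom density may not be integrable or 'upper' is too low")
      m1 <- sum(tab$w * tab$g * tab$t) / m0
      m2 <- sum(tab$w * tab$g * tab$t^2) / m0
      c(mean = m1, cv2 = (m2 - m1^2) / m1^2)
    })
})

# quadrature table (t, w, g) for any continuous family, used for R-side
# moments and CDF construction
.quadTab <- function(model) {
  if (model@family == "custom") return(.customTab(model))
  if (model@family == "delta") stop("no quadrature for the delta family")
  tab <- .builtinGrid(model)
  list(t = tab$t, w = tab$w,
       g = cpp_density(.familyCode(model), .familyParams(model), tab$t))
}

# composite GL grid matching the supports used in the C++ core
.builtinGrid <- function(model) {
  p <- model@params
  rng <- switch(model@family,
    exponential = c(0, 140 * p[["T"]]),
    erlang = c(0, (p[["N"]] + 40 * sqrt(p[["N"]]) + 140) / p[["lambda"]]),
    beta_exponential = c(0, 140 / (p[["beta"]] * p[["n0"]])),
    { # growth-rate heterogeneity / fluctuating threshold
      b0 <- p[["beta0"]]; sb <- p[["sigma_beta"]]
      sx <- if (model@family == "fluctuating_threshold") p[["sigma_X"]] else 0
      lo <- max(log(2) - 13 * sx, log(2) / 100) / (b0 + 13 * sb)
      c(lo / 5, 60 * log(2) / b0)
    })
  gl <- cpp_gl_nodes(32L)
  npan <- 64L
  edges <- exp(seq(log(max(rng[1], rng[2] * 1e-6)), log(rng[2]),
                   length.out = npan + 1L))
  edges[1] <- rng[1]
  t <- w <- numeric(0)
  for (i in seq_len(npan)) {
    h <- (edges[i + 1L] - edges[i]) / 2
    t <- c(t, edges[i] + h * (gl$x + 1))
    w <- c(w, h * gl$w)
  }
  list(t = t, w = w)
}

#' Laplace transform of the division-time density
#'
#' `L(s) = E[exp(-s ts)]`, the only statistic of the division-time law that
#' enters the protein coefficient recursion. Closed forms are used for the
#' delta, exponential, Erlang and beta-exponential families; the remaining
#' families use quadrature.
#'
#' @param model a [DivisionTimeModel-class].
#' @param s non-negative rate(s) (1/min).
#' @return L(s) in (0, 1].
#' @export
setMethod("dtLaplace", "DivisionTimeModel", function(model, s) {
  if (any(s < 0)) stop("s must be >= 0")
  cpp_laplace(.familyCode(model), .familyParams(model), s,
              tab = .modelTab(model))
})

#' Mixed exponential integrals entering the mRNA recursion
#'
#' `Psi[k, j] = E[exp(-j gamma ts) (1 - exp(-gamma ts))^(k - j)]`. The
#' integrand is non-negative, so the quadrature used here is free of the
#' cancellation that plagues the equivalent alternating binomial expansion
#' into Laplace values.
#'
#' @param model a [DivisionTimeModel-class].
#' @param k,j integer orders with 0 <= j <= k.
#' @param gamma decay rate (1/min), > 0.
#' @return Psi value in \[0, 1\].
#' @export
setMethod("dtPsi", "DivisionTimeModel", function(model, k, j, gamma) {
  if (j > k || j < 0) stop("need 0 <= j <= k")
  if (gamma <= 0) stop("gamma must be > 0")
  P <- cpp_psi(.familyCode(model), .familyParams(model), gamma, as.integer(k),
               tab = .modelTab(model))
  P[k + 1L, j + 1L]
})

#' Calibrate the beta-exponential growth rate to a target mean
#'
#' The first-passage mean of the autocatalytic process from n0 to the
#' threshold X is the harmonic sum `T = (1/beta) * sum_{s=n0}^{X-1} 1/s`, so
#' the rate reproducing a target mean is `beta = sum(1/s) / target_mean`.
#'
#' @param X threshold copy number.
#' @param n0 initial copy number, 0 < n0 < X.
#' @param target_mean desired mean division time (minutes).
#' @return A calibrated [DivisionTimeModel-class] of family
#'   `beta_exponential`.
#' @examples
#' m <- calibrateBetaExponential(X = 20, n0 = 10, target_mean = 20)
#' dtMoments(m) # mean 20, CV^2 ~ 0.104
#' @export
calibrateBetaExponential <- function(X, n0, target_mean) {
  if (target_mean <= 0) stop("target_mean must be > 0")
  if (n0 <= 0 || n0 >= X) stop("need 0 < n0 < X")
  beta <- sum(1 / (n0:(X - 1))) / target_mean
  betaExponentialModel(X = X, n0 = n0, beta = beta)
}

# survival function P(ts > tau) per family
.survivalFunction <- function(model) {
  p <- model@params
  switch(model@family,
    delta = function(tau) as.numeric(tau < p[["T"]]),
    exponential = function(tau) exp(-tau / p[["T"]]),
    erlang = function(tau) pgamma(tau, shape = p[["N"]], rate = p[["lambda"]],
                                  lower.tail = FALSE),
    beta_exponential = function(tau)
      pbeta(exp(-p[["beta"]] * tau), p[["n0"]], p[["X"]] - p[["n0"]]),
    growth_rate_heterogeneity = function(tau)
      pnorm(log(2) / tau, p[["beta0"]], p[["sigma_beta"]]) -
        pnorm(0, p[["beta0"]], p[["sigma_beta"]]),
    { # fluctuating threshold / custom: numeric CDF on the quadrature grid
      tab <- .quadTab(model)
      cdf <- cumsum(tab$w * tab$g)
      tot <- cdf[length(cdf)]
      function(tau) {
        s <- 1 - approx(tab$t, cdf, xout = tau, yleft = 0, yright = tot,
                        rule = 2)$y
        pmax(s, 0)
      }
    })
}

#' Powell age weight for an exponentially growing population
#'
#' Computes the population growth exponent `vm` as the root of
#' `2 L(vm) = 1` (bracketed root search on the monotone Laplace transform)
#' and returns the age density
#' `phi(tau) = 2 vm exp(-vm tau) P(ts > tau)`.
#'
#' @param model a [DivisionTimeModel-class] with finite mean.
#' @return An [AgeWeight-class] object.
#' @examples
#' w <- powellAgeWeight(erlangModel(3, 0.15))
#' w@vm   # equals 0.15 * (2^(1/3) - 1)
#' @export
setMethod("powellAgeWeight", "DivisionTimeModel", function(model) {
  mts <- dtMoments(model)[["mean"]]
  f <- function(v) 2 * dtLaplace(model, v) - 1
  upperBr <- 10 * log(2) / mts
  if (f(upperBr) > 0) stop("failed to bracket the growth exponent")
  vm <- uniroot(f, c(1e-12 / mts, upperBr), tol = 1e-14 / mts)$root
  surv <- .survivalFunction(model)
  phi <- function(tau) 2 * vm * exp(-vm * tau) * surv(tau)
  nrm <- integrate(phi, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
  new("AgeWeight", vm = vm, survival = surv, model = model, normCheck = nrm)
})

#' Age density phi(tau) of an age weight
#'
#' @param weight an [AgeWeight-class].
#' @param tau ages (minutes).
#' @return phi(tau) values.
#' @export
ageDensity <- function(weight, tau)
  2 * weight@vm * exp(-weight@vm * tau) * weight@survival(tau)

# inverse-CDF sampling grid for families without a direct sampler
.samplerGrid <- function(model) {
  tab <- .quadTab(model)
  o <- order(tab$t)
  x <- tab$t[o]
  cdf <- cumsum((tab$w * tab$g)[o])
  keep <- !duplicated(cdf)
  list(x = x[keep], cdf = cdf[keep])
}

#' Draw random division times
#'
#' Sampling uses the structural representation of each family: Erlang as a
#' sum of N exponential stages, beta-exponential as the first-passage sum of
#' X - n0 exponential stages with rates beta*s, growth-rate heterogeneity as
#' `ln 2 / beta` with Gaussian beta, and inverse-CDF lookup on a quadrature
#' grid for the fluctuating-threshold family (and custom models without a
#' sampler). With `eps > 0` successive draws are AR(1)-mixed as
#' `ts_i = (1 - eps) * draw + eps * ts_{i-1}`, preserving the long-run mean.
#'
#' @param model a [DivisionTimeModel-class].
#' @param n number of draws.
#' @param eps correlation parameter in \[0, 1).
#' @return Numeric vector of n division times.
#' @export
setMethod("dtSample", "DivisionTimeModel", function(model, n, eps = 0) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (model@family == "custom" && is.function(model@sampler) && eps == 0)
    return(model@sampler(n))
  grid <- if (model@family %in% c("fluctuating_threshold", "custom"))
    .samplerGrid(model) else NULL
  cpp_next_division_times(.familyCode(model), .familyParams(model),
                          as.integer(n), eps, grid = grid)
})

#' @rdname dtSample
#' @export
nextDivisionTimes <- function(model, n, eps = 0) dtSample(model, n, eps)
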