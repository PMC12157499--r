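# shared fixtures: the four division-time laws with mean 20 min used
# throughout (fixed, first-passage threshold, Erlang with 3 stages,
# exponential), and the kinetic parameter sets of the worked examples

mrnaPars <- function() geneParams(0.5, gammaM = 0.05)
proteinPars <- function() geneParams(0.5, b = 2, gammaP = 0.01)

fourModels <- function() {
  list(delta = deltaModel(20),
       beta_exponential = calibrateBetaExponential(20, 10, 20),
       erlang = erlangModel(3, 0.15),
       exponential = exponentialModel(20))
}

# independent oracle: exponential-division-time mRNA distribution in closed
# form, P(m) = sum_k C(k,m) (-1)^(k-m) (km_eff)^k prod_i 1/(1/T + gm i - 2^-i/T)
eq23ClosedForm <- function(m, kmEff, T, gm, Kmax = 400) {
  logden <- c(0, cumsum(log(1 / T + gm * (1:Kmax) - 2^-(1:Kmax) / T)))
  vapply(m, function(mm) {
    k <- mm:Kmax
    lw <- lchoose(k, mm) + k * log(kmEff) - logden[k + 1]
    sum((-1)^(k - mm) * exp(lw))
  }, numeric(1))
}

# independent oracle: fixed-division-time protein generating function as an
# infinite product; returns the Taylor coefficients of F about q = q0
# (q0 = 1 gives F^(k)(1)/k!, q0 = 0 gives the PMF itself)
deltaProteinSeries <- function(q0, K, a, b, gp, T, nfac = 2000) {
  E <- exp(-gp * T)
  i <- 1:nfac
  u <- exp(-i * log(2) + (i - 1) * log(E))
  anum <- 1 - b * u * E * (q0 - 1)
  aden <- 1 - b * u * (q0 - 1)
  bnum <- b * u * E / anum
  bden <- b * u / aden
  lg <- numeric(K + 1)
  lg[1] <- a * sum(log(anum) - log(aden))
  for (m in 1:K) lg[m + 1] <- a * sum(bden^m - bnum^m) / m
  f <- numeric(K + 1)
  f[1] <- exp(lg[1])
  for (k in 1:K) f[k + 1] <- sum((1:k) * lg[2:(k + 1)] * f[k:1]) / k
  f
}
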