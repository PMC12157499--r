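setMethod("show", "DivisionTimeModel", function(object) {
  cat("DivisionTimeModel:", object@family, "\n")
  if (length(object@params))
    cat("  params:", paste(names(object@params), signif(object@params, 6),
                           sep = " = ", collapse = ", "), "\n")
  m <- tryCatch(dtMoments(object), error = function(e) NULL)
  if (!is.null(m))
    cat(sprintf("  mean %.4g min, CV^2 %.4g\n", m[["mean"]], m[["cv2"]]))
})

setMethod("show", "GeneParams", function(object) {
  cat("GeneParams (rates in 1/min):\n")
  cat(sprintf("  km = %g, gammaM = %g, b = %g, gammaP = %g\n", object@km,
              object@gammaM, object@b, object@gammaP))
  if (!is.na(object@gammaP))
    cat(sprintf("  a = km/gammaP = %g\n", object@km / object@gammaP))
})

setMethod("show", "CoefficientTable", function(object) {
  cat(sprintf("CoefficientTable: %s, K = %d%s\n", object@species, object@K,
              if (is.na(object@age)) " (birth state)"
              else sprintf(" (age %.4g min)", object@age)))
  cat("  division times:", object@model@family, "\n")
  k <- min(object@K, 3L)
  v <- object@sign[seq_len(k + 1)] * exp(object@loge[seq_len(k + 1)])
  cat("  first coefficients:", paste(signif(v, 6), collapse = ", "), "\n")
})

setMethod("show", "PMFResult", function(object) {
  cat(sprintf("PMFResult: state '%s'%s, support 0..%d, method %s\n",
              object@state,
              if (is.na(object@age)) "" else sprintf(" (tau = %g)", object@age),
              max(object@support), object@method))
  cat(sprintf("  total mass %.8f (K = %d, %d negatives clipped)\n",
              sum(object@probabilities), object@convergence$K,
              object@convergence$nClipped))
})

setMethod("show", "NoiseSummary", function(object) {
  cat("NoiseSummary:\n")
  cat(sprintf("  mean %.6g, variance %.6g, kappa3 %.6g\n", object@mean,
              object@variance, object@kappa3))
  cat(sprintf("  CV^2 %.6g, skewness %.6g\n", object@cv2, object@skewness))
})

setMethod("show", "DecompositionResult", function(object) {
  cat("Protein noise decomposition (CV^2 at birth):\n")
  cat(sprintf("  total %.4f = BP %.4f + DT %.4f + GE %.4f\n", object@cv2Total,
              object@cv2BP, object@cv2DT, object@cv2GE))
  cat(sprintf("  shares: BP %d%%, DT %d%%, GE %d%%\n",
              round(object@shares[["BP"]]), round(object@shares[["DT"]]),
              round(object@shares[["GE"]])))
})

setMethod("show", "AgeWeight", function(object) {
  cat(sprintf("Powell age weight: vm = %.6g /min (model %s)\n", object@vm,
              object@model@family))
  cat(sprintf("  integral of phi over (0, Inf): %.8f\n", object@normCheck))
})

setMethod("show", "CountHistogram", function(object) {
  cat(sprintf("CountHistogram: state '%s', %d samples, counts 0..%d\n",
              object@state, object@nSamples, length(object@counts) - 1L))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s, %d histories x %d recorded cycles (burn-in %d)\n",
              object@species, object@nHistories, object@recordCycles,
              object@burnInCycles))
  if (object@eps > 0) cat("  correlated division times, eps =", object@eps, "\n")
})
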