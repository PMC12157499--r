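#' @rdname dtDensity
#' @export
setGeneric("dtDensity", function(model, ts) standardGeneric("dtDensity"))

#' @rdname dtMoments
#' @export
setGeneric("dtMoments", function(model) standardGeneric("dtMoments"))

#' @rdname dtLaplace
#' @export
setGeneric("dtLaplace", function(model, s) standardGeneric("dtLaplace"))

#' @rdname dtPsi
#' @export
setGeneric("dtPsi", function(model, k, j, gamma) standardGeneric("dtPsi"))

#' @rdname dtSample
#' @export
setGeneric("dtSample", function(model, n, eps = 0) standardGeneric("dtSample"))

#' @rdname powellAgeWeight
#' @export
setGeneric("powellAgeWeight", function(model) standardGeneric("powellAgeWeight"))

#' @rdname cumulants
#' @export
setGeneric("cumulants", function(table) standardGeneric("cumulants"))

#' @rdname pmfAtBirth
#' @export
setGeneric("pmfAtBirth",
  function(table, ymax = NULL, ...) standardGeneric("pmfAtBirth"))

#' @rdname pmfBeforeDivision
#' @export
setGeneric("pmfBeforeDivision",
  function(table, ymax = NULL, ...) standardGeneric("pmfBeforeDivision"))

#' @rdname ageCoefficients
#' @export
setGeneric("ageCoefficients",
  function(table, tau) standardGeneric("ageCoefficients"))

#' @rdname pmfAtAge
#' @export
setGeneric("pmfAtAge",
  function(table, tau, ymax = NULL, ...) standardGeneric("pmfAtAge"))

#' @rdname ageAveragedPmf
#' @export
setGeneric("ageAveragedPmf",
  function(table, weight, ymax = NULL, ...) standardGeneric("ageAveragedPmf"))

#' @rdname simulateLineage
#' @export
setGeneric("simulateLineage", function(config, ...)
  standardGeneric("simulateLineage"))
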