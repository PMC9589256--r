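#' @name psmediation-accessors
#' @title Accessors for psmediation classes
#' @description Accessor generics for the S4 containers: study variables of a
#'   [MediationDataset], components of a fitted [PropensityResult],
#'   [ScreenResult], [McpFit] and [MediationResult].
#' @param x an object of the documented class.
#' @return The requested component (vector, matrix or data.frame).
NULL

#' @rdname psmediation-accessors
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))

#' @rdname psmediation-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname psmediation-accessors
#' @export
setGeneric("mediators", function(x) standardGeneric("mediators"))

#' @rdname psmediation-accessors
#' @export
setGeneric("confounders", function(x) standardGeneric("confounders"))

#' @rdname psmediation-accessors
#' @export
setGeneric("trueAlpha", function(x) standardGeneric("trueAlpha"))

#' @rdname psmediation-accessors
#' @export
setGeneric("trueBeta", function(x) standardGeneric("trueBeta"))

#' @rdname psmediation-accessors
#' @export
setGeneric("psScores", function(x) standardGeneric("psScores"))

#' @rdname psmediation-accessors
#' @export
setGeneric("psWeights", function(x) standardGeneric("psWeights"))

#' @rdname psmediation-accessors
#' @export
setGeneric("psCoef", function(x) standardGeneric("psCoef"))

#' @rdname psmediation-accessors
#' @export
setGeneric("keptMediators", function(x) standardGeneric("keptMediators"))

#' @rdname psmediation-accessors
#' @export
setGeneric("marginalBeta", function(x) standardGeneric("marginalBeta"))

#' @rdname psmediation-accessors
#' @export
setGeneric("mcpSupport", function(x) standardGeneric("mcpSupport"))

#' @rdname psmediation-accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname psmediation-accessors
#' @export
setGeneric("directEffect", function(x) standardGeneric("directEffect"))

#' @rdname psmediation-accessors
#' @export
setGeneric("significantMediators",
           function(x) standardGeneric("significantMediators"))
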