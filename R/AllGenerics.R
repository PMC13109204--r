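#' Accessors for patchPo classes
#'
#' Small accessor generics exposing the slots of the pipeline objects;
#' user code should use these rather than \code{@} access.
#'
#' @param x a patchPo object.
#' @return The corresponding component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("baselineMean", function(x) standardGeneric("baselineMean"))
#' @rdname accessors
#' @export
setGeneric("unitaryAmplitude", function(x) standardGeneric("unitaryAmplitude"))
#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))
#' @rdname accessors
#' @export
setGeneric("componentSigmas", function(x) standardGeneric("componentSigmas"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setGeneric("anchoring", function(x) standardGeneric("anchoring"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("pOpen", function(x) standardGeneric("pOpen"))
#' @rdname accessors
#' @export
setGeneric("openCount", function(x) standardGeneric("openCount"))
#' @rdname accessors
#' @export
setGeneric("simTrace", function(x) standardGeneric("simTrace"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' Convert a result object to a plain list for reporting
#'
#' Used by [writeReport()] to serialize pipeline objects to JSON.
#'
#' @param x a patchPo result object.
#' @return A named list of plain R values.
#' @export
setGeneric("asReportList", function(x) standardGeneric("asReportList"))
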