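# Accessor methods, show methods, asReportList methods.

#' @rdname accessors
setMethod("samples", "Trace", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "Trace", function(x) x@samplingRate)
#' @rdname accessors
setMethod("traceUnits", "Trace", function(x) x@units)
#' @rdname accessors
setMethod("startTime", "Trace", function(x) x@startTime)
#' @rdname accessors
setMethod("traceDuration", "Trace",
          function(x) length(x@samples) / x@samplingRate)

#' @rdname accessors
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname accessors
setMethod("epochs", "TevcSimulation", function(x) x@epochs)

#' @rdname accessors
setMethod("binCenters", "AmplitudeHistogram",
          function(x) (x@breaks[-1L] + x@breaks[-length(x@breaks)]) / 2)
#' @rdname accessors
setMethod("binCounts", "AmplitudeHistogram", function(x) x@counts)
#' @rdname accessors
setMethod("binWidth", "AmplitudeHistogram", function(x) x@binWidth)

#' @rdname accessors
setMethod("baselineMean", "GmmFit", function(x) x@mu0)
#' @rdname accessors
setMethod("unitaryAmplitude", "GmmFit", function(x) x@unitaryAmplitude)
#' @rdname accessors
setMethod("componentWeights", "GmmFit", function(x) x@weights)
#' @rdname accessors
setMethod("componentSigmas", "GmmFit", function(x) x@sigmas)
#' @rdname accessors
setMethod("rSquared", "GmmFit", function(x) x@rSquared)

#' @rdname accessors
setMethod("occupancies", "OccupancyProfile", function(x) x@probs)
#' @rdname accessors
setMethod("anchoring", "OccupancyProfile", function(x) x@anchoring)

#' @rdname accessors
setMethod("nChannels", "BinomialFit", function(x) x@nChannels)
#' @rdname accessors
setMethod("pOpen", "BinomialFit", function(x) x@pOpen)
#' @rdname accessors
setMethod("rSquared", "BinomialFit", function(x) x@rSquared)
#' @rdname accessors
setMethod("occupancies", "BinomialFit", function(x) x@observed)

#' @rdname accessors
setMethod("openCount", "PatchSimulation", function(x) x@openCount)
#' @rdname accessors
setMethod("simTrace", "PatchSimulation", function(x) x@trace)
#' @rdname accessors
setMethod("simConfig", "PatchSimulation", function(x) x@config)
#' @rdname accessors
setMethod("simTrace", "TevcSimulation", function(x) x@trace)
#' @rdname accessors
setMethod("simConfig", "TevcSimulation", function(x) x@config)

#' @rdname accessors
setMethod("pOpen", "PoEstimate", function(x) x@pOpen)
#' @rdname accessors
setMethod("rSquared", "PoEstimate",
          function(x) if (is.null(x@fit)) NA_real_ else x@fit@rSquared)
#' @rdname accessors
setMethod("nChannels", "PoEstimate",
          function(x) if (is.null(x@fit)) NA_integer_ else x@fit@nChannels)
#' @rdname accessors
setMethod("unitaryAmplitude", "PoEstimate",
          function(x) if (is.null(x@gmm)) NA_real_ else x@gmm@unitaryAmplitude)

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples @ %g Hz (%.3f s), units %s\n",
              length(object@samples), object@samplingRate,
              traceDuration(object), object@units))
  cat(sprintf("  range [%.4g, %.4g] %s", min(object@samples),
              max(object@samples), object@units))
  if (nzchar(object@channelLabel))
    cat(sprintf("  label '%s'", object@channelLabel))
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet with %d epoch(s)\n", nrow(object@epochs)))
  if (nrow(object@epochs)) print(object@epochs)
})

setMethod("show", "AmplitudeHistogram", function(object) {
  cat(sprintf(
    "AmplitudeHistogram: %d bins of width %g, %d points, range [%.4g, %.4g]\n",
    length(object@counts), object@binWidth, sum(object@counts),
    min(object@breaks), max(object@breaks)))
})

setMethod("show", "GmmFit", function(object) {
  k <- length(object@weights)
  cat(sprintf("GmmFit: %d equidistant Gaussian component(s)\n", k))
  cat(sprintf("  mu0 = %.4g, unitary amplitude i = %.4g, R^2 = %.5f\n",
              object@mu0, object@unitaryAmplitude, object@rSquared))
  cat("  weights:", paste(signif(object@weights, 4), collapse = ", "), "\n")
  if (!object@converged)
    cat("  [optimizer did not report convergence: ", object@message, "]\n")
})

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf("OccupancyProfile (%s): P_k = %s\n", object@anchoring,
              paste(signif(object@probs, 4), collapse = ", ")))
})

setMethod("show", "BinomialFit", function(object) {
  cat(sprintf("BinomialFit: N = %d, Po = %.4f, R^2 = %.5f (%s, %s)\n",
              object@nChannels, object@pOpen, object@rSquared,
              object@anchoring, object@objective))
})

setMethod("show", "PatchSimulation", function(object) {
  cat("PatchSimulation\n")
  cat(sprintf("  N = %d channel(s), true Po = %g, i = %g pA\n",
              object@config$nChannels, object@config$pOpen,
              object@config$unitaryAmplitude))
  show(object@trace)
})

setMethod("show", "TevcSimulation", function(object) {
  cat("TevcSimulation\n")
  show(object@trace)
  show(object@epochs)
})

setMethod("show", "PoEstimate", function(object) {
  cat(sprintf("PoEstimate: %d level(s) detected, Po = %.4f\n",
              object@nLevels, object@pOpen))
  if (!is.null(object@gmm))
    cat(sprintf("  unitary amplitude i = %.4g, binomial N = %d, R^2 = %.5f\n",
                object@gmm@unitaryAmplitude, nChannels(object),
                rSquared(object)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "TevcResult", function(object) {
  cat("TevcResult\n")
  if (nrow(object@deltaIAmi)) print(object@deltaIAmi)
  cat(sprintf("  fold change = %.4g, relative activity = %.4g\n",
              object@foldChange, object@relativeActivity))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname asReportList
setMethod("asReportList", "BinomialFit", function(x) {
  list(type = "BinomialFit", n_channels = x@nChannels, p_open = x@pOpen,
       r_squared = x@rSquared, predicted = x@predicted,
       observed = x@observed, level_map = x@levelMap,
       anchoring = x@anchoring, objective = x@objective)
})

#' @rdname asReportList
setMethod("asReportList", "GmmFit", function(x) {
  list(type = "GmmFit", mu0 = x@mu0, unitary_amplitude = x@unitaryAmplitude,
       sigmas = x@sigmas, weights = x@weights, r_squared = x@rSquared,
       converged = x@converged)
})

#' @rdname asReportList
setMethod("asReportList", "OccupancyProfile", function(x) {
  list(type = "OccupancyProfile", probs = x@probs, anchoring = x@anchoring,
       total_weight = x@totalWeight)
})

#' @rdname asReportList
setMethod("asReportList", "PoEstimate", function(x) {
  list(type = "PoEstimate", n_levels = x@nLevels, p_open = x@pOpen,
       flags = x@flags,
       gmm = if (is.null(x@gmm)) NULL else asReportList(x@gmm),
       occupancy = if (is.null(x@occupancy)) NULL else
         asReportList(x@occupancy),
       binomial = if (is.null(x@fit)) NULL else asReportList(x@fit))
})

#' @rdname asReportList
setMethod("asReportList", "TevcResult", function(x) {
  list(type = "TevcResult", delta_i_ami = x@deltaIAmi,
       fold_change = x@foldChange, relative_activity = x@relativeActivity,
       flags = x@flags)
})

#' @rdname asReportList
setMethod("asReportList", "ANY", function(x) x)
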