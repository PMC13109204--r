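#' @import methods
NULL

.TRACE_UNITS <- c("pA", "uA", "nA")

#' Trace: a uniformly sampled time--current series
#'
#' Container for a single continuous current recording: a numeric vector of
#' current samples together with the sampling rate, the current units and an
#' optional start time and channel label. Patch-clamp recordings are
#' conventionally stored in pA (inward current negative), whole-cell TEVC
#' recordings in uA.
#'
#' @slot samples numeric vector of current values; finite, length >= 1.
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot units one of \code{"pA"}, \code{"uA"}, \code{"nA"}.
#' @slot channelLabel free-text label for the recording.
#' @slot startTime time of the first sample in seconds.
#'
#' @seealso [Trace()] for the user constructor, [readTrace()], [writeTrace()].
#' @exportClass Trace
setClass("Trace",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    units = "character",
    channelLabel = "character",
    startTime = "numeric"
  ),
  prototype(
    samples = numeric(0), samplingRate = 1, units = "pA",
    channelLabel = "", startTime = 0
  )
)

setValidity("Trace", function(object) {
  msg <- character(0)
  if (length(object@samples) < 1L)
    msg <- c(msg, "trace must contain at least one sample")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "trace samples must all be finite")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@units) != 1L || !(object@units %in% .TRACE_UNITS))
    msg <- c(msg, sprintf("units must be one of: %s",
                          paste(.TRACE_UNITS, collapse = ", ")))
  if (length(object@startTime) != 1L || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param samples numeric vector of current values (finite).
#' @param samplingRate sampling rate in Hz.
#' @param units current units, one of \code{"pA"}, \code{"uA"}, \code{"nA"}.
#' @param channelLabel optional recording label.
#' @param startTime time of the first sample in seconds.
#' @return A [Trace-class] object.
#' @examples
#' tr <- Trace(rnorm(100, sd = 0.05), samplingRate = 10000)
#' traceDuration(tr)
#' @export
Trace <- function(samples, samplingRate, units = "pA",
                  channelLabel = "", startTime = 0) {
  new("Trace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      units = as.character(units),
      channelLabel = as.character(channelLabel),
      startTime = as.numeric(startTime))
}

#' EpochSet: labeled time intervals over a recording
#'
#' An ordered set of half-open intervals \code{[start, end)} in seconds, each
#' carrying a label from an extensible vocabulary (baseline, lowNa, highNa,
#' amiloride, protease, mtset, washout) and a conductance scale factor used by
#' the whole-cell simulator. Intervals sharing a label must not overlap.
#'
#' @slot epochs data.frame with columns \code{label}, \code{start},
#'   \code{end}, \code{scale}.
#' @seealso [EpochSet()], [readEpochs()], [deltaIAmi()].
#' @exportClass EpochSet
setClass("EpochSet", representation(epochs = "data.frame"),
         prototype(epochs = data.frame(label = character(0),
                                       start = numeric(0),
                                       end = numeric(0),
                                       scale = numeric(0))))

setValidity("EpochSet", function(object) {
  ep <- object@epochs
  need <- c("label", "start", "end", "scale")
  if (!all(need %in% names(ep)))
    return(sprintf("epochs must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(ep) == 0L) return(TRUE)
  msg <- character(0)
  if (any(!is.finite(ep$start)) || any(!is.finite(ep$end)))
    msg <- c(msg, "epoch boundaries must be finite")
  if (any(ep$start < 0))
    msg <- c(msg, "epoch start times must be >= 0")
  if (any(ep$end <= ep$start))
    msg <- c(msg, "each epoch must satisfy start < end")
  # overlap check within each label track (half-open intervals)
  for (lab in unique(ep$label)) {
    sub <- ep[ep$label == lab, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)] - 1e-12))
      msg <- c(msg, sprintf("overlapping epochs in label track '%s'", lab))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param label character vector of epoch labels.
#' @param start,end numeric vectors of epoch boundaries in seconds; intervals
#'   are half-open \code{[start, end)}.
#' @param scale per-epoch conductance scale factors (default 1); used by
#'   [simulateTevcTrace()] to model e.g. low-sodium bath solutions.
#' @return An [EpochSet-class] object, sorted by start time.
#' @examples
#' EpochSet(c("highNa", "amiloride"), start = c(0, 60), end = c(60, 90))
#' @export
EpochSet <- function(label = character(0), start = numeric(0),
                     end = numeric(0), scale = 1) {
  n <- length(label)
  ep <- data.frame(label = as.character(label),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   scale = rep_len(as.numeric(scale), n),
                   stringsAsFactors = FALSE)
  ep <- ep[order(ep$start), , drop = FALSE]
  rownames(ep) <- NULL
  new("EpochSet", epochs = ep)
}

#' AmplitudeHistogram: binned current amplitudes
#'
#' Histogram of sampled current values at a fixed bin width (default 0.01 pA
#' for patch recordings). Bin edges are uniform and chosen so that the first
#' bin is centered on the minimum sample, which keeps quantized (noise-free)
#' current levels on bin centers.
#'
#' @slot breaks numeric vector of bin edges, strictly increasing, uniform.
#' @slot counts non-negative integer counts per bin; sums to the number of
#'   samples binned.
#' @slot binWidth bin width in the trace units.
#' @seealso [buildAmplitudeHistogram()], [fitConstrainedGmm()].
#' @exportClass AmplitudeHistogram
setClass("AmplitudeHistogram",
  representation(breaks = "numeric", counts = "numeric", binWidth = "numeric"))

setValidity("AmplitudeHistogram", function(object) {
  msg <- character(0)
  if (length(object@breaks) != length(object@counts) + 1L)
    msg <- c(msg, "breaks must have length(counts) + 1 entries")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  d <- diff(object@breaks)
  if (any(d <= 0))
    msg <- c(msg, "breaks must be strictly increasing")
  if (length(d) && max(abs(d - object@binWidth)) > 1e-8 * object@binWidth)
    msg <- c(msg, "breaks must be uniform with spacing binWidth")
  if (length(msg)) msg else TRUE
})

#' GmmFit: equidistant-constrained Gaussian mixture fit
#'
#' Result of fitting a sum of Gaussian components to an amplitude histogram
#' under the structural constraint that component means are integer multiples
#' of a single unitary amplitude above the baseline mean:
#' mu_k = mu0 + k * i, k = 0..N. Weights are expressed as the number of
#' sample points attributed to each component.
#'
#' @slot mu0 baseline (all channels closed) mean current.
#' @slot unitaryAmplitude signed single-channel current i (negative = inward).
#' @slot sigmas per-component standard deviations (> 0).
#' @slot weights per-component point counts A_k (>= 0).
#' @slot rSquared coefficient of determination of the fitted curve vs counts.
#' @slot residuals per-bin residuals (counts - fitted).
#' @slot fitted per-bin fitted counts.
#' @slot converged logical; FALSE when the optimizer stopped without meeting
#'   its convergence test (the best attempt is still returned).
#' @slot message optimizer diagnostic.
#' @seealso [fitConstrainedGmm()], [occupationProbabilities()].
#' @exportClass GmmFit
setClass("GmmFit",
  representation(mu0 = "numeric", unitaryAmplitude = "numeric",
                 sigmas = "numeric", weights = "numeric",
                 rSquared = "numeric", residuals = "numeric",
                 fitted = "numeric", converged = "logical",
                 message = "character"))

setValidity("GmmFit", function(object) {
  msg <- character(0)
  if (length(object@sigmas) != length(object@weights))
    msg <- c(msg, "sigmas and weights must have equal length")
  if (any(object@sigmas <= 0)) msg <- c(msg, "sigmas must be positive")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' OccupancyProfile: level occupation probabilities
#'
#' Probabilities P_k that exactly k channels are simultaneously open, indexed
#' from the baseline level outward, obtained by normalizing the Gaussian
#' component weights. The anchoring convention records whether the baseline
#' level is assumed fully closed (\code{baseline_closed}) or the most extreme
#' observed level fully open (\code{top_open}).
#'
#' @slot probs numeric vector of occupation probabilities, sums to 1.
#' @slot anchoring \code{"baseline_closed"} or \code{"top_open"}.
#' @slot totalWeight total point count the probabilities were computed from.
#' @seealso [occupationProbabilities()], [fitBinomialPo()].
#' @exportClass OccupancyProfile
setClass("OccupancyProfile",
  representation(probs = "numeric", anchoring = "character",
                 totalWeight = "numeric"))

setValidity("OccupancyProfile", function(object) {
  msg <- character(0)
  if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "occupation probabilities must sum to 1 (within 1e-9)")
  if (any(object@probs < -1e-12) || any(object@probs > 1 + 1e-12))
    msg <- c(msg, "occupation probabilities must lie in [0, 1]")
  if (!object@anchoring %in% c("baseline_closed", "top_open"))
    msg <- c(msg, "anchoring must be 'baseline_closed' or 'top_open'")
  if (length(msg)) msg else TRUE
})

#' BinomialFit: binomial occupancy model fit
#'
#' Least-squares fit of observed level occupation probabilities to the
#' binomial distribution B(k | Po, N) for N independent, identical channels.
#'
#' @slot nChannels assumed channel count N.
#' @slot pOpen fitted per-channel open probability in [0, 1].
#' @slot rSquared coefficient of determination of the fit.
#' @slot predicted dbinom(0:N, N, pOpen); sums to 1.
#' @slot observed observed probabilities mapped onto k = 0..N (unobserved
#'   levels carry 0 under the penalized objective).
#' @slot levelMap integer vector: open-channel count k assigned to each
#'   observed level index (baseline first).
#' @slot anchoring anchoring convention used for the mapping.
#' @slot objective \code{"penalized"} (unobserved intermediate levels count
#'   as observed probability 0) or \code{"observed_only"}.
#' @seealso [fitBinomialPo()], [scanChannelCount()].
#' @exportClass BinomialFit
setClass("BinomialFit",
  representation(nChannels = "integer", pOpen = "numeric",
                 rSquared = "numeric", predicted = "numeric",
                 observed = "numeric", levelMap = "integer",
                 anchoring = "character", objective = "character"))

setValidity("BinomialFit", function(object) {
  msg <- character(0)
  if (object@pOpen < 0 || object@pOpen > 1)
    msg <- c(msg, "pOpen must lie in [0, 1]")
  if (abs(sum(object@predicted) - 1) > 1e-9)
    msg <- c(msg, "predicted binomial probabilities must sum to 1")
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' PatchSimulation: a simulated on-cell patch recording
#'
#' Bundles the simulated noisy (optionally filtered) trace with the latent
#' per-sample count of open channels and the generating configuration.
#'
#' @slot trace the simulated [Trace-class].
#' @slot openCount integer vector, per-sample number of open channels.
#' @slot config the [patchSimConfig()] list used for generation.
#' @seealso [simulatePatchTrace()].
#' @exportClass PatchSimulation
setClass("PatchSimulation",
  representation(trace = "Trace", openCount = "integer", config = "list"))

#' TevcSimulation: a simulated whole-cell (TEVC) recording
#'
#' @slot trace the simulated [Trace-class] (units uA, 20 Hz by default).
#' @slot epochs the [EpochSet-class] protocol the trace was generated under.
#' @slot config the [tevcSimConfig()] list used for generation.
#' @seealso [simulateTevcTrace()].
#' @exportClass TevcSimulation
setClass("TevcSimulation",
  representation(trace = "Trace", epochs = "EpochSet", config = "list"))

#' PoEstimate: full single-channel pipeline result
#'
#' Result of [estimatePoFromTrace()]: the amplitude histogram, the
#' equidistant-constrained Gaussian mixture fit, the occupancy profile and the
#' binomial fit, together with the detected level count and any flags raised
#' (e.g. \code{"no open levels detected"} on a silent trace).
#'
#' @slot histogram the [AmplitudeHistogram-class].
#' @slot gmm the [GmmFit-class], or NULL when no levels were fit.
#' @slot occupancy the [OccupancyProfile-class], or NULL.
#' @slot fit the [BinomialFit-class], or NULL.
#' @slot nLevels detected number of current levels.
#' @slot pOpen the estimated open probability (0 when no open levels).
#' @slot flags character vector of warnings raised during estimation.
#' @exportClass PoEstimate
setClass("PoEstimate",
  representation(histogram = "AmplitudeHistogram", gmm = "ANY",
                 occupancy = "ANY", fit = "ANY", nLevels = "integer",
                 pOpen = "numeric", flags = "character"))

#' TevcResult: whole-cell analysis result
#'
#' Amiloride-sensitive current fractions and the derived estimators computed
#' from an epoch-annotated TEVC trace.
#'
#' @slot deltaIAmi data.frame with one row per amiloride application
#'   (columns: label, amiStart, amiEnd, meanBefore, meanDuring, delta).
#' @slot foldChange ratio of the second to the first amiloride-sensitive
#'   current (NA when fewer than two applications).
#' @slot relativeActivity ratio of the first to the second amiloride-sensitive
#'   current (the MTSET estimator; NA when fewer than two applications).
#' @slot flags character vector of analysis warnings.
#' @seealso [analyzeTevc()], [relativeActivity()], [foldChange()].
#' @exportClass TevcResult
setClass("TevcResult",
  representation(deltaIAmi = "data.frame", foldChange = "numeric",
                 relativeActivity = "numeric", flags = "character"))
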