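# Binomial occupancy inference: converts Gaussian component weights into
# level occupation probabilities, fits a per-channel open probability under
# an assumed channel count N, and scans candidate N.

#' Occupation probabilities from a Gaussian mixture fit
#'
#' Normalizes the fitted component point counts: P_k = A_k / sum_j A_j,
#' ordered from the baseline level outward.
#'
#' @param fit a [GmmFit-class], or a numeric vector of non-negative weights
#'   (baseline first).
#' @param anchoring interpretation of the observed levels:
#'   \code{"baseline_closed"} (default; all channels closed at the baseline
#'   level) or \code{"top_open"} (all channels open at the most extreme
#'   observed level).
#' @return An [OccupancyProfile-class]; probabilities sum to 1 within 1e-9.
#' @examples
#' occupationProbabilities(c(20, 80))   # P = (0.2, 0.8)
#' @export
occupationProbabilities <- function(fit,
                                    anchoring = c("baseline_closed",
                                                  "top_open")) {
  anchoring <- match.arg(anchoring)
  w <- if (is(fit, "GmmFit")) fit@weights else as.numeric(fit)
  if (length(w) < 1L || any(w < 0))
    stop("input error: weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("input error: all component weights are zero")
  new("OccupancyProfile", probs = w / tot, anchoring = anchoring,
      totalWeight = tot)
}

# open-channel count assigned to each observed level index (baseline first)
# under an assumed channel count N.
.levelMap <- function(K, N, anchoring) {
  if (N < K - 1L)
    stop(sprintf(
      "mapping error: N = %d is smaller than the %d observed open level(s)",
      N, K - 1L))
  if (anchoring == "baseline_closed" || K == 1L) return(0:(K - 1L))
  # top_open: baseline assumed fully closed at index 0, the most extreme
  # observed level carries all N channels; observed levels keep unit spacing
  # below the top, so index j >= 1 maps to N - K + 1 + j.
  c(0L, N - K + 1L + seq_len(K - 1L))
}

#' Fit the per-channel open probability by a binomial occupancy model
#'
#' For N independent identical channels the probability that exactly k are
#' open is B(k | Po, N) = choose(N, k) Po^k (1 - Po)^(N - k). The fit
#' minimizes the sum of squared differences between observed occupation
#' probabilities (mapped onto k = 0..N by the anchoring convention) and
#' B(k | Po, N). Under the default \code{"penalized"} objective, levels in
#' 0..N with no observed counterpart enter with observed probability 0 (they
#' were genuinely not observed); \code{"observed_only"} restricts the sum to
#' mapped levels. Po is located on a grid of resolution 1e-4 and refined by
#' golden-section search; for N = 1 the closed-form least-squares minimizer
#' is used. R^2 is 1 - SS_res/SS_tot with SS_tot taken about the mean of the
#' observed probabilities entering the objective.
#'
#' @param occ an [OccupancyProfile-class] (or numeric probability vector,
#'   baseline first, interpreted with \code{anchoring}).
#' @param nChannels assumed channel count N (>= observed open levels).
#' @param objective \code{"penalized"} (default) or \code{"observed_only"}.
#' @param anchoring used only when \code{occ} is a bare numeric vector.
#' @return A [BinomialFit-class].
#' @examples
#' fit <- fitBinomialPo(occupationProbabilities(c(20, 80)), 1)
#' pOpen(fit)     # 0.8
#' rSquared(fit)  # 1
#' @export
fitBinomialPo <- function(occ, nChannels,
                          objective = c("penalized", "observed_only"),
                          anchoring = c("baseline_closed", "top_open")) {
  objective <- match.arg(objective)
  if (!is(occ, "OccupancyProfile"))
    occ <- occupationProbabilities(occ, anchoring = match.arg(anchoring))
  N <- as.integer(nChannels)
  if (N < 1L) stop("nChannels must be >= 1")
  P <- occ@probs
  K <- length(P)
  map <- .levelMap(K, N, occ@anchoring)
  obs <- numeric(N + 1L)
  obs[map + 1L] <- P
  useK <- if (objective == "penalized") 0:N else map
  obsUse <- obs[useK + 1L]

  sse <- function(p) sum((obsUse - stats::dbinom(useK, N, p))^2)
  if (N == 1L && length(useK) == 2L) {
    # closed form: d/dp [(obs0 - (1-p))^2 + (obs1 - p)^2] = 0
    pHat <- min(1, max(0, (1 - obs[1L] + obs[2L]) / 2))
  } else {
    grid <- seq(0, 1, by = 1e-4)
    g <- vapply(grid, sse, numeric(1))
    j <- which.min(g)
    lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
    pHat <- if (opt$objective <= g[j]) opt$minimum else grid[j]
    pHat <- min(1, max(0, pHat))
  }
  ssRes <- sse(pHat)
  ssTot <- sum((obsUse - mean(obsUse))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else as.numeric(ssRes < 1e-24)
  new("BinomialFit", nChannels = N, pOpen = pHat, rSquared = r2,
      predicted = stats::dbinom(0:N, N, pHat), observed = obs,
      levelMap = as.integer(map), anchoring = occ@anchoring,
      objective = objective)
}

#' Scan candidate channel counts
#'
#' Repeats the binomial fit for each assumed channel count N in
#' \code{nMin:nMax} and tabulates (N, Po, R^2). Under baseline_closed
#' anchoring the fitted Po decreases (non-increasing) as the assumed N
#' grows; under top_open it increases.
#'
#' @param occ an [OccupancyProfile-class] or probability vector.
#' @param nMin,nMax channel-count range; \code{nMin} defaults to the number
#'   of observed open levels.
#' @param ... passed to [fitBinomialPo()].
#' @return A data.frame with columns \code{N}, \code{pOpen}, \code{rSquared}
#'   ordered by N; the individual [BinomialFit-class] objects are attached
#'   as the \code{"fits"} attribute.
#' @examples
#' occ <- occupationProbabilities(c(20, 80), anchoring = "top_open")
#' scanChannelCount(occ, nMax = 3)
#' @export
scanChannelCount <- function(occ, nMin = NULL, nMax, ...) {
  if (!is(occ, "OccupancyProfile")) occ <- occupationProbabilities(occ)
  if (is.null(nMin)) nMin <- length(occ@probs) - 1L
  nMin <- max(1L, as.integer(nMin))
  nMax <- as.integer(nMax)
  if (nMax < nMin) stop("nMax must be >= nMin")
  fits <- lapply(nMin:nMax, function(N) fitBinomialPo(occ, N, ...))
  out <- data.frame(N = nMin:nMax,
                    pOpen = vapply(fits, function(f) f@pOpen, numeric(1)),
                    rSquared = vapply(fits, function(f) f@rSquared,
                                      numeric(1)))
  attr(out, "fits") <- fits
  out
}

#' Pick the channel count with the best binomial fit
#'
#' @param scan result of [scanChannelCount()].
#' @return The smallest N attaining the maximal R^2 (ties broken toward
#'   smaller N).
#' @export
bestChannelCount <- function(scan) {
  stopifnot(is.data.frame(scan), all(c("N", "rSquared") %in% names(scan)))
  scan$N[which.max(scan$rSquared)]
}

#' Estimate the open probability from a raw patch-clamp trace
#'
#' Runs the full single-channel pipeline: amplitude histogram (0.01 pA bins
#' by default), level detection, equidistant-constrained Gaussian mixture
#' fit, occupation probabilities, and the binomial fit at an assumed channel
#' count. By default N is the number of observed open levels (the minimum
#' channel count that explains the observable levels); pass \code{nChannels}
#' to fix it. A trace with a single detected level (no openings) returns
#' Po = 0 with the flag \code{"no open levels detected"}.
#'
#' @param trace a [Trace-class] or numeric vector (pA).
#' @param binWidth histogram bin width (default 0.01 pA).
#' @param nChannels assumed channel count N, or NULL to use the detected
#'   open-level count.
#' @param anchoring \code{"baseline_closed"} (default) or \code{"top_open"}.
#' @param objective binomial objective, see [fitBinomialPo()].
#' @param sharedSigma constrain the Gaussian components to one shared sigma.
#' @param baselineEnd baseline peak convention, see [detectLevels()].
#' @return A [PoEstimate-class] with all intermediates.
#' @examples
#' sim <- simulatePatchTrace(patchSimConfig(
#'   nChannels = 1, pOpen = 0.8, duration = 5, seed = 3))
#' est <- estimatePoFromTrace(simTrace(sim))
#' pOpen(est)   # close to 0.8
#' @export
estimatePoFromTrace <- function(trace, binWidth = 0.01, nChannels = NULL,
                                anchoring = c("baseline_closed", "top_open"),
                                objective = c("penalized", "observed_only"),
                                sharedSigma = FALSE,
                                baselineEnd = c("max", "min")) {
  anchoring <- match.arg(anchoring)
  objective <- match.arg(objective)
  baselineEnd <- match.arg(baselineEnd)
  hist <- buildAmplitudeHistogram(trace, binWidth = binWidth)
  det <- detectLevels(hist, baselineEnd = baselineEnd)
  if (det$nLevels == 1L && is.null(nChannels)) {
    return(new("PoEstimate", histogram = hist, gmm = NULL, occupancy = NULL,
               fit = NULL, nLevels = 1L, pOpen = 0,
               flags = "no open levels detected"))
  }
  flags <- character(0)
  N <- if (is.null(nChannels)) det$nLevels - 1L else as.integer(nChannels)
  # Under baseline_closed with an explicit N, give the mixture N + 1
  # components so faint outer levels missed by peak detection can still
  # acquire weight; under top_open only the observed levels are modelled
  # (the assumed extra channels sit in unobserved intermediate levels).
  K <- if (anchoring == "baseline_closed") N + 1L else det$nLevels
  if (K != det$nLevels)
    flags <- c(flags, sprintf("fit used %d components; %d levels detected",
                              K, det$nLevels))
  gmm <- fitConstrainedGmm(hist, nComponents = K,
                           init = list(mu0 = det$mu0, i = det$i),
                           sharedSigma = sharedSigma,
                           baselineEnd = baselineEnd)
  if (!gmm@converged) flags <- c(flags, "GMM fit did not converge")
  occ <- occupationProbabilities(gmm, anchoring = anchoring)
  fit <- fitBinomialPo(occ, N, objective = objective)
  new("PoEstimate", histogram = hist, gmm = gmm, occupancy = occ, fit = fit,
      nLevels = det$nLevels, pOpen = fit@pOpen, flags = flags)
}
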