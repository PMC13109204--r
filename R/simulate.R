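# Two-state Markov gating simulator: on-cell patch traces from N independent
# identical channels, and macroscopic whole-cell (TEVC) traces with epoch
# protocols (amiloride, protease, MTSET, run-down).

#' Configuration for the on-cell patch simulator
#'
#' Describes a membrane patch holding \code{nChannels} independent, identical
#' two-state (closed/open) channels. Gating rates are derived from the
#' stationary open probability and the mean open dwell time:
#' closing rate = 1 / meanOpenDwell and opening rate =
#' pOpen / ((1 - pOpen) * meanOpenDwell), so that the stationary
#' P(open) equals \code{pOpen} for each channel.
#'
#' @param nChannels positive integer, number of channels N in the patch.
#' @param pOpen true per-channel open probability in [0, 1].
#' @param meanOpenDwell mean open dwell time in seconds (> 0). Default 0.5 s,
#'   in the slow-gating regime typical of ENaC; dwell times must stay well
#'   above the rise time of the digital filter or brief sojourns are
#'   attenuated below detectability.
#' @param unitaryAmplitude signed single-channel current i in pA
#'   (negative = inward). Default -0.35 pA.
#' @param baselineCurrent baseline (all-closed) current mu0 in pA.
#' @param noiseSd Gaussian noise standard deviation in pA (>= 0).
#' @param samplingRate sampling rate in Hz. Default 10 kHz.
#' @param filterCutoff -3 dB cutoff of the zero-phase Gaussian digital filter
#'   in Hz, or NULL for no filtering. Default 100 Hz (0.1 kHz).
#' @param duration recording duration in seconds.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return A validated configuration list of class \code{patchSimConfig}.
#' @seealso [simulatePatchTrace()]
#' @export
patchSimConfig <- function(nChannels, pOpen, meanOpenDwell = 0.5,
                           unitaryAmplitude = -0.35, baselineCurrent = 0,
                           noiseSd = 0.05, samplingRate = 10000,
                           filterCutoff = 100, duration = 60, seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single integer 'seed' is required")
  if (length(nChannels) != 1L || nChannels < 1 || nChannels != round(nChannels))
    stop("nChannels must be a positive integer")
  if (length(pOpen) != 1L || !is.finite(pOpen) || pOpen < 0 || pOpen > 1)
    stop("pOpen must lie in [0, 1]")
  if (!is.finite(meanOpenDwell) || meanOpenDwell <= 0)
    stop("meanOpenDwell must be a positive dwell time in seconds")
  if (!is.finite(noiseSd) || noiseSd < 0)
    stop("noiseSd must be >= 0")
  if (!is.finite(samplingRate) || samplingRate <= 0)
    stop("samplingRate must be positive")
  if (!is.null(filterCutoff) &&
      (!is.finite(filterCutoff) || filterCutoff <= 0))
    stop("filterCutoff must be positive or NULL")
  if (!is.finite(duration) || duration * samplingRate < 1)
    stop("duration * samplingRate must be >= 1 sample")
  structure(list(nChannels = as.integer(nChannels), pOpen = pOpen,
                 meanOpenDwell = meanOpenDwell,
                 unitaryAmplitude = unitaryAmplitude,
                 baselineCurrent = baselineCurrent, noiseSd = noiseSd,
                 samplingRate = samplingRate, filterCutoff = filterCutoff,
                 duration = duration, seed = as.integer(seed)),
            class = c("patchSimConfig", "list"))
}

# Sample one discrete-time two-state gating path of length n.
# Per-step switch probabilities follow 1 - exp(-rate * dt): exact for the
# two-state chain observed at sample resolution. Sojourns are drawn as
# geometric run lengths, which is equivalent to per-step Bernoulli switching
# but orders of magnitude faster.
.gatingPath <- function(n, pOpen, meanOpenDwell, dt) {
  if (pOpen <= 0) return(integer(n))
  if (pOpen >= 1) return(rep.int(1L, n))
  kClose <- 1 / meanOpenDwell
  kOpen <- pOpen / ((1 - pOpen) * meanOpenDwell)
  qLeaveOpen <- 1 - exp(-kClose * dt)
  qLeaveClosed <- 1 - exp(-kOpen * dt)
  state <- as.integer(stats::runif(1) < pOpen)
  out <- integer(n)
  filled <- 0L
  while (filled < n) {
    # draw a batch of alternating sojourn lengths starting from `state`
    need <- n - filled
    nSoj <- max(8L, ceiling(2 * need / (0.5 / qLeaveOpen + 0.5 / qLeaveClosed)))
    states <- if (state == 1L) rep_len(c(1L, 0L), nSoj) else rep_len(c(0L, 1L), nSoj)
    q <- ifelse(states == 1L, qLeaveOpen, qLeaveClosed)
    len <- stats::rgeom(nSoj, q) + 1L
    reps <- rep.int(states, len)
    take <- min(length(reps), need)
    out[(filled + 1L):(filled + take)] <- reps[seq_len(take)]
    filled <- filled + take
    # state to resume from: the state after the last *complete* batch; if the
    # batch covered the trace we are done, otherwise continue from the state
    # following the last sojourn drawn
    state <- if (states[nSoj] == 1L) 0L else 1L
  }
  out
}

#' Zero-phase Gaussian low-pass filter
#'
#' Symmetric (zero-phase) Gaussian FIR filter with -3 dB amplitude at the
#' requested cutoff frequency; edges are handled by reflection so the output
#' has the same length as the input. This emulates the digital Gaussian
#' filtering routinely applied to patch-clamp recordings: no overshoot or
#' ringing.
#'
#' @param x numeric vector of samples.
#' @param samplingRate sampling rate in Hz.
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @return Filtered numeric vector, same length as \code{x}.
#' @export
gaussianLowpass <- function(x, samplingRate, cutoff) {
  if (cutoff >= samplingRate / 2) return(x)
  sigmaS <- sqrt(log(2)) / (2 * pi * cutoff) * samplingRate  # samples
  h <- max(1L, ceiling(4 * sigmaS))
  k <- stats::dnorm(seq(-h, h), sd = sigmaS)
  k <- k / sum(k)
  n <- length(x)
  hh <- min(h, n - 1L)
  pre <- x[seq(hh + 1L, 2L, length.out = hh)]
  post <- x[seq(n - 1L, n - hh, length.out = hh)]
  if (hh < h) {  # very short traces: pad further with edge values
    pre <- c(rep(x[1L], h - hh), pre)
    post <- c(post, rep(x[n], h - hh))
  }
  xp <- c(pre, x, post)
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(h + 1L):(h + n)])
}

#' Simulate an on-cell patch-clamp recording
#'
#' Generates a current trace from N independent identical two-state channels:
#' each sample equals mu0 + k * i + Gaussian noise, where k is the number of
#' simultaneously open channels at that sample, followed by optional
#' zero-phase Gaussian low-pass filtering. The latent open-channel count is
#' returned alongside the trace so recovery can be checked against ground
#' truth.
#'
#' @param config a [patchSimConfig()] object.
#' @return A [PatchSimulation-class] holding the trace (class
#'   [Trace-class]), the per-sample latent open count, and the config.
#' @examples
#' sim <- simulatePatchTrace(patchSimConfig(
#'   nChannels = 1, pOpen = 0.8, duration = 2, seed = 1))
#' mean(openCount(sim))   # close to 0.8
#' @export
simulatePatchTrace <- function(config) {
  stopifnot(inherits(config, "patchSimConfig"))
  set.seed(config$seed)
  n <- round(config$duration * config$samplingRate)
  dt <- 1 / config$samplingRate
  count <- integer(n)
  for (ch in seq_len(config$nChannels))
    count <- count + .gatingPath(n, config$pOpen, config$meanOpenDwell, dt)
  y <- config$baselineCurrent + count * config$unitaryAmplitude
  if (config$noiseSd > 0) y <- y + stats::rnorm(n, sd = config$noiseSd)
  if (!is.null(config$filterCutoff))
    y <- gaussianLowpass(y, config$samplingRate, config$filterCutoff)
  tr <- Trace(y, samplingRate = config$samplingRate, units = "pA",
              channelLabel = sprintf("sim patch N=%d Po=%g seed=%d",
                                     config$nChannels, config$pOpen,
                                     config$seed))
  new("PatchSimulation", trace = tr, openCount = count,
      config = unclass(config))
}

#' Configuration for the whole-cell (TEVC) simulator
#'
#' Describes a macroscopic recording from an oocyte expressing a large
#' population of identical channels. The macroscopic current is
#' leak + n * i * Po(t) * block(t) * scale(t) * rundown(t) + noise, where the
#' amiloride block, the per-epoch conductance scale and the protease/MTSET
#' effects on Po are driven by the epoch schedule.
#'
#' Epoch semantics: \code{amiloride} epochs block the channel population
#' (residual fraction \code{amilorideResidual}, default 0 = complete block);
#' \code{protease} epochs model the incubation in protease plus amiloride
#' (blocked during the epoch; from the epoch start onward the per-channel
#' open probability is multiplied by \code{proteasePoMultiplier}, clamped to
#' [0, 1]); from the start of an \code{mtset} epoch onward the open
#' probability becomes \code{pOpenAfterMtset} and the unitary conductance is
#' multiplied by \code{mtsetConductanceFactor}. Any epoch's \code{scale}
#' column scales the conducting current (e.g. ~0 for a low-Na bath).
#'
#' @param epochs an [EpochSet-class] (or data.frame with label/start/end and
#'   optional scale); epochs must not overlap.
#' @param nChannels effective whole-cell channel count (scale factor).
#' @param unitaryCurrent per-channel current in uA-equivalent units (signed).
#' @param pOpenBaseline baseline per-channel open probability in [0, 1].
#' @param pOpenAfterMtset open probability after MTSET modification
#'   (default 1).
#' @param proteasePoMultiplier multiplier applied to the open probability
#'   after a protease epoch (>= 0; result clamped to [0, 1]).
#' @param rundownRate run-down as a fraction of current lost per minute
#'   (>= 0); the conducting current is multiplied by
#'   (1 - rundownRate)^(t / 60).
#' @param leakCurrent amiloride-insensitive leak in uA.
#' @param amilorideResidual residual unblocked fraction during amiloride
#'   (default 0 = complete block).
#' @param mtsetConductanceFactor unitary-conductance factor applied from the
#'   MTSET epoch onward (default 1 = conductance unchanged).
#' @param noiseSd Gaussian noise SD in uA (>= 0).
#' @param samplingRate sampling rate in Hz (default 20).
#' @param duration recording length in seconds; defaults to the end of the
#'   last epoch.
#' @param seed integer RNG seed.
#' @return A validated configuration list of class \code{tevcSimConfig}.
#' @seealso [simulateTevcTrace()], [makeTevcEpochs()]
#' @export
tevcSimConfig <- function(epochs, nChannels = 1e6, unitaryCurrent = -5e-6,
                          pOpenBaseline = 0.4, pOpenAfterMtset = 1,
                          proteasePoMultiplier = 1, rundownRate = 0,
                          leakCurrent = 0, amilorideResidual = 0,
                          mtsetConductanceFactor = 1, noiseSd = 0,
                          samplingRate = 20, duration = NULL, seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single integer 'seed' is required")
  if (is.data.frame(epochs)) {
    if (is.null(epochs$scale)) epochs$scale <- 1
    epochs <- EpochSet(epochs$label, epochs$start, epochs$end, epochs$scale)
  }
  stopifnot(is(epochs, "EpochSet"))
  ep <- epochs@epochs
  if (nrow(ep) > 1L) {
    o <- order(ep$start)
    if (any(ep$start[o][-1L] < ep$end[o][-nrow(ep)] - 1e-12))
      stop("schedule error: epochs overlap")
  }
  if (is.null(duration)) duration <- if (nrow(ep)) max(ep$end) else 1
  if (nrow(ep) && max(ep$end) > duration + 1e-12)
    stop("schedule error: epochs extend beyond the trace duration")
  if (pOpenBaseline < 0 || pOpenBaseline > 1 ||
      pOpenAfterMtset < 0 || pOpenAfterMtset > 1)
    stop("open probabilities must lie in [0, 1]")
  if (proteasePoMultiplier < 0) stop("proteasePoMultiplier must be >= 0")
  if (rundownRate < 0 || rundownRate >= 1)
    stop("rundownRate must lie in [0, 1) (fraction lost per minute)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(epochs = epochs, nChannels = nChannels,
                 unitaryCurrent = unitaryCurrent,
                 pOpenBaseline = pOpenBaseline,
                 pOpenAfterMtset = pOpenAfterMtset,
                 proteasePoMultiplier = proteasePoMultiplier,
                 rundownRate = rundownRate, leakCurrent = leakCurrent,
                 amilorideResidual = amilorideResidual,
                 mtsetConductanceFactor = mtsetConductanceFactor,
                 noiseSd = noiseSd, samplingRate = samplingRate,
                 duration = duration, seed = as.integer(seed)),
            class = c("tevcSimConfig", "list"))
}

#' Simulate a whole-cell TEVC recording under an epoch protocol
#'
#' @param config a [tevcSimConfig()] object.
#' @return A [TevcSimulation-class] with the trace, the epoch schedule and
#'   the configuration.
#' @examples
#' ep <- makeTevcEpochs("mtset")
#' sim <- simulateTevcTrace(tevcSimConfig(ep, pOpenBaseline = 0.94, seed = 1))
#' analyzeTevc(simTrace(sim), epochs(sim))
#' @export
simulateTevcTrace <- function(config) {
  stopifnot(inherits(config, "tevcSimConfig"))
  set.seed(config$seed)
  n <- round(config$duration * config$samplingRate)
  t <- (seq_len(n) - 1L) / config$samplingRate
  ep <- config$epochs@epochs

  po <- rep(config$pOpenBaseline, n)
  cond <- rep(1, n)
  # chronological protease / MTSET effects (persist from epoch start onward)
  for (j in seq_len(nrow(ep))[order(ep$start)]) {
    if (ep$label[j] == "protease") {
      po[t >= ep$start[j]] <-
        min(1, max(0, config$pOpenBaseline * config$proteasePoMultiplier))
    } else if (ep$label[j] == "mtset") {
      po[t >= ep$start[j]] <- config$pOpenAfterMtset
      cond[t >= ep$start[j]] <- config$mtsetConductanceFactor
    }
  }
  block <- rep(1, n)
  scale <- rep(1, n)
  for (j in seq_len(nrow(ep))) {
    inEp <- t >= ep$start[j] & t < ep$end[j]
    scale[inEp] <- ep$scale[j]
    if (ep$label[j] %in% c("amiloride", "protease"))
      block[inEp] <- config$amilorideResidual
  }
  rundown <- (1 - config$rundownRate)^(t / 60)
  y <- config$leakCurrent +
    config$nChannels * config$unitaryCurrent * po * cond * block * scale *
      rundown
  if (config$noiseSd > 0) y <- y + stats::rnorm(n, sd = config$noiseSd)
  tr <- Trace(y, samplingRate = config$samplingRate, units = "uA",
              channelLabel = sprintf("sim TEVC seed=%d", config$seed))
  new("TevcSimulation", trace = tr, epochs = config$epochs,
      config = unclass(config))
}

#' Standard whole-cell protocols
#'
#' Builds the epoch schedule of the two routine TEVC protocols: the protease
#' activation protocol (amiloride application, 5 min incubation in protease
#' plus amiloride, second amiloride application) and the MTSET protocol
#' (amiloride application, MTSET exposure, second amiloride application).
#' All plateau epochs are long enough for a trailing 5 s analysis window.
#'
#' @param kind \code{"protease"} or \code{"mtset"}.
#' @param plateau duration in seconds of the conducting plateaus (default 60).
#' @param amiloride duration of amiloride applications (default 30).
#' @param incubation duration of the protease incubation or MTSET exposure
#'   (default 300 for protease, 120 for MTSET).
#' @return An [EpochSet-class].
#' @export
makeTevcEpochs <- function(kind = c("protease", "mtset"), plateau = 60,
                           amiloride = 30, incubation = NULL) {
  kind <- match.arg(kind)
  if (is.null(incubation)) incubation <- if (kind == "protease") 300 else 120
  t0 <- 0
  lab <- character(0); s <- numeric(0); e <- numeric(0)
  add <- function(l, d) {
    lab <<- c(lab, l); s <<- c(s, t0); e <<- c(e, t0 + d); t0 <<- t0 + d
  }
  add("highNa", plateau)
  add("amiloride", amiloride)
  add("highNa", plateau)
  add(if (kind == "protease") "protease" else "mtset", incubation)
  add("highNa", plateau)
  add("amiloride", amiloride)
  add("washout", plateau / 2)
  EpochSet(lab, s, e)
}
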