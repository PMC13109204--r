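# Amplitude-histogram construction and the equidistant-constrained Gaussian
# mixture fit: recovers the baseline mean mu0, the unitary amplitude i, and
# per-component weights A_k from the histogram of a single-channel recording.

#' Build an amplitude histogram from a trace
#'
#' Bins the current samples at a fixed bin width (default 0.01 pA, the
#' conventional resolution for ENaC single-channel records). Bin edges are
#' uniform with the first bin centered on the minimum sample, so that
#' noise-free quantized levels fall exactly on bin centers.
#'
#' @param trace a [Trace-class] or numeric vector of current samples.
#' @param binWidth bin width in trace units (> 0). Default 0.01.
#' @return An [AmplitudeHistogram-class].
#' @examples
#' tr <- Trace(rnorm(1000, sd = 0.05), 10000)
#' buildAmplitudeHistogram(tr)
#' @export
buildAmplitudeHistogram <- function(trace, binWidth = 0.01) {
  x <- if (is(trace, "Trace")) trace@samples else as.numeric(trace)
  if (length(x) == 0L) stop("input error: empty trace")
  if (!is.finite(binWidth) || binWidth <= 0)
    stop("binWidth must be a positive number")
  lo <- min(x); hi <- max(x)
  nbins <- max(1L, as.integer(floor((hi - lo) / binWidth + 0.5)) + 1L)
  left <- lo - binWidth / 2
  # guard against the max sample landing on/over the last edge
  while (left + nbins * binWidth <= hi) nbins <- nbins + 1L
  idx <- pmin(pmax(floor((x - left) / binWidth) + 1L, 1L), nbins)
  counts <- tabulate(idx, nbins)
  new("AmplitudeHistogram", breaks = left + (0:nbins) * binWidth,
      counts = as.numeric(counts), binWidth = binWidth)
}

# box smoothing used only for peak picking
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 9L) return(v)
  (c(v[1L], v[-n]) + v + c(v[-1L], v[n])) / 3
}

#' Detect equidistant current levels in an amplitude histogram
#'
#' Level counting proceeds in two stages. Strong peaks -- local maxima whose
#' bin count reaches \code{minProminence} of the largest bin -- fix the level
#' spacing (the median distance between neighbouring strong peaks, enforcing
#' a minimum separation of half that spacing). The equidistant grid implied
#' by the spacing is then extended outward from the baseline, accepting
#' weaker local maxima (bin count >= \code{minCount}) that sit at grid
#' positions; this recovers sparsely occupied outer levels (e.g. the level
#' at which all six channels of a low-Po patch are simultaneously open)
#' that hold far less than \code{minProminence} of the modal level.
#'
#' The baseline is taken as the detected peak nearest the least-inward
#' current (the algebraic maximum for inward currents); pass
#' \code{baselineEnd = "min"} for outward (positive-going) openings.
#'
#' @param hist an [AmplitudeHistogram-class].
#' @param minProminence fraction of the maximum bin count a strong peak must
#'   reach (default 0.05).
#' @param minCount absolute bin-count floor for grid-extension peaks
#'   (default 20).
#' @param baselineEnd \code{"max"} (baseline at the least-negative peak,
#'   inward currents) or \code{"min"}.
#' @return A list with \code{nLevels} (>= 1), \code{mu0} (initial baseline
#'   mean), \code{i} (initial unitary amplitude: signed median peak spacing,
#'   0 when only one level), and \code{peaks} (detected peak positions).
#' @seealso [fitConstrainedGmm()]
#' @export
detectLevels <- function(hist, minProminence = 0.05, minCount = 20,
                         baselineEnd = c("max", "min")) {
  stopifnot(is(hist, "AmplitudeHistogram"))
  baselineEnd <- match.arg(baselineEnd)
  counts <- hist@counts
  ctr <- binCenters(hist)
  nb <- length(counts)
  if (nb == 1L || sum(counts) == 0)
    return(list(nLevels = 1L, mu0 = ctr[which.max(counts)], i = 0,
                peaks = ctr[which.max(counts)]))
  s <- .smooth3(counts)
  isMax <- s >= c(-Inf, s[-nb]) & s > c(s[-1L], -Inf)
  cand <- which(isMax & counts >= minProminence * max(counts))
  if (length(cand) == 0L) cand <- which.max(counts)
  if (length(cand) == 1L) {
    # no spacing information: single level
    return(list(nLevels = 1L, mu0 = ctr[cand], i = 0, peaks = ctr[cand]))
  }
  spacing <- stats::median(diff(sort(ctr[cand])))
  # enforce minimum separation 0.5 * spacing, keeping taller peaks
  keep <- integer(0)
  for (j in cand[order(-counts[cand])]) {
    if (!length(keep) || all(abs(ctr[j] - ctr[keep]) >= 0.5 * spacing))
      keep <- c(keep, j)
  }
  keep <- sort(keep)
  if (length(keep) > 1L) spacing <- stats::median(diff(ctr[keep]))
  peaks <- ctr[keep]
  mu0 <- if (baselineEnd == "max") max(peaks) else min(peaks)
  iHat <- if (baselineEnd == "max") -spacing else spacing
  kOf <- round((peaks - mu0) / iHat)
  kMax <- max(kOf)
  # grid extension: walk outward accepting weak local maxima on the grid
  halfWin <- max(1L, as.integer(round(0.3 * spacing / hist@binWidth)))
  repeat {
    target <- mu0 + (kMax + 1L) * iHat
    jc <- which.min(abs(ctr - target))
    win <- max(1L, jc - halfWin):min(nb, jc + halfWin)
    jbest <- win[which.max(counts[win])]
    ok <- counts[jbest] >= minCount &&
      s[jbest] >= s[max(1L, jbest - 1L)] &&
      s[jbest] >= s[min(nb, jbest + 1L)] &&
      abs(ctr[jbest] - target) <= 0.45 * spacing
    if (!ok) break
    kMax <- kMax + 1L
    peaks <- c(peaks, ctr[jbest])
  }
  list(nLevels = as.integer(kMax + 1L), mu0 = mu0, i = iHat,
       peaks = sort(peaks))
}

# per-cluster stats from assigning bins to the nearest level of the grid
.clusterStats <- function(hist, mu0, iHat, K) {
  ctr <- binCenters(hist)
  counts <- hist@counts
  k <- pmin(pmax(round((ctr - mu0) / iHat), 0), K - 1L)
  out <- lapply(0:(K - 1L), function(kk) {
    sel <- k == kk & counts > 0
    A <- sum(counts[sel])
    if (A == 0) return(list(A = 0, m = mu0 + kk * iHat, sd = 0))
    m <- sum(counts[sel] * ctr[sel]) / A
    list(A = A, m = m, sd = sqrt(sum(counts[sel] * (ctr[sel] - m)^2) / A))
  })
  list(A = vapply(out, `[[`, numeric(1), "A"),
       m = vapply(out, `[[`, numeric(1), "m"),
       sd = vapply(out, `[[`, numeric(1), "sd"))
}

# initial per-component weights/sigmas by assigning bins to the nearest level
.initComponents <- function(hist, mu0, iHat, K) {
  ctr <- binCenters(hist)
  counts <- hist@counts
  if (K == 1L) {
    m <- sum(counts * ctr) / sum(counts)
    s2 <- sum(counts * (ctr - m)^2) / max(1, sum(counts))
    return(list(A = sum(counts), sigma = max(sqrt(s2), hist@binWidth / 2)))
  }
  k <- pmin(pmax(round((ctr - mu0) / iHat), 0), K - 1L)
  A <- vapply(0:(K - 1L), function(kk) sum(counts[k == kk]), numeric(1))
  # width of the best-populated level as the common sigma init
  kk <- which.max(A) - 1L
  sel <- k == kk
  m <- sum(counts[sel] * ctr[sel]) / max(1, sum(counts[sel]))
  s2 <- sum(counts[sel] * (ctr[sel] - m)^2) / max(1, sum(counts[sel]))
  list(A = pmax(A, 0), sigma = max(sqrt(s2), hist@binWidth / 2))
}

.gmmModel <- function(par, centers, bw, K, sharedSigma) {
  mu0 <- par[1L]; iHat <- par[2L]
  if (sharedSigma) {
    sig <- rep(par[3L], K)
    A <- par[4L:(3L + K)]
  } else {
    sig <- par[3L:(2L + K)]
    A <- par[(3L + K):(2L + 2L * K)]
  }
  mu <- mu0 + (0:(K - 1L)) * iHat
  m <- numeric(length(centers))
  for (kk in seq_len(K))
    m <- m + A[kk] * bw / (sqrt(2 * pi) * sig[kk]) *
      exp(-0.5 * ((centers - mu[kk]) / sig[kk])^2)
  m
}

#' Fit an equidistant-constrained sum of Gaussians to an amplitude histogram
#'
#' Least-squares fit of per-bin counts to a sum of Gaussian components whose
#' means are structurally constrained to mu_k = mu0 + k * i (k = 0..K-1):
#' free parameters are the baseline mean mu0, the unitary amplitude i, the
#' per-component standard deviations sigma_k (optionally shared) and the
#' per-component point counts A_k >= 0. Each component is evaluated as
#' density at the bin center times the bin width. Fitting uses
#' Levenberg--Marquardt ([minpack.lm::nls.lm]) started from peak detection,
#' with a fixed sequence of jittered restarts on failure; the best attempt is
#' always returned.
#'
#' @param hist an [AmplitudeHistogram-class].
#' @param nComponents number of components K = N + 1; defaults to the levels
#'   found by [detectLevels()].
#' @param init optional list with elements \code{mu0} and \code{i} overriding
#'   peak-detection initialization.
#' @param sharedSigma logical; constrain all components to one sigma
#'   (default FALSE, matching the free-sigma model).
#' @param baselineEnd passed to [detectLevels()].
#' @param maxRestarts number of jittered restarts on non-convergence.
#' @return A [GmmFit-class]. Non-convergence after restarts raises a warning
#'   and returns the best attempt with \code{converged = FALSE}.
#' @examples
#' sim <- simulatePatchTrace(patchSimConfig(
#'   nChannels = 1, pOpen = 0.8, duration = 5, seed = 2))
#' fit <- fitConstrainedGmm(buildAmplitudeHistogram(simTrace(sim)))
#' unitaryAmplitude(fit)   # close to -0.35
#' @export
fitConstrainedGmm <- function(hist, nComponents = NULL, init = NULL,
                              sharedSigma = FALSE,
                              baselineEnd = c("max", "min"),
                              maxRestarts = 5L) {
  stopifnot(is(hist, "AmplitudeHistogram"))
  baselineEnd <- match.arg(baselineEnd)
  det <- detectLevels(hist, baselineEnd = baselineEnd)
  if (is.null(nComponents)) nComponents <- det$nLevels
  K <- as.integer(nComponents)
  if (K < 1L) stop("nComponents must be >= 1")
  mu0 <- if (!is.null(init$mu0)) init$mu0 else det$mu0
  iHat <- if (!is.null(init$i)) init$i else det$i
  if (K > 1L && (!is.finite(iHat) || iHat == 0))
    stop(sprintf(
      "fit error: %d components requested but no level spacing detected", K))
  counts <- hist@counts
  ctr <- binCenters(hist)
  bw <- hist@binWidth

  if (K == 1L) {
    ini <- .initComponents(hist, mu0, 1, 1L)
    fn <- function(p) counts - p[3L] * bw / (sqrt(2 * pi) * p[2L]) *
      exp(-0.5 * ((ctr - p[1L]) / p[2L])^2)
    fit <- minpack.lm::nls.lm(
      par = c(mu0, ini$sigma, ini$A), fn = fn,
      lower = c(-Inf, bw / 5, 0),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    fitted <- counts - fn(fit$par)
    ssRes <- sum((counts - fitted)^2)
    ssTot <- sum((counts - mean(counts))^2)
    return(new("GmmFit", mu0 = fit$par[1L], unitaryAmplitude = 0,
               sigmas = fit$par[2L], weights = fit$par[3L],
               rSquared = if (ssTot > 0) 1 - ssRes / ssTot else
                 as.numeric(ssRes == 0),
               residuals = counts - fitted, fitted = fitted,
               converged = fit$info %in% 1:3, message = fit$message))
  }

  # Quasi-discrete histograms (each level essentially one bin wide, as for a
  # noise-free quantized trace) make the Gaussian location parameters
  # unidentifiable within a bin for the least-squares optimizer; the level
  # means and weights are then computed directly from the bin clusters and
  # mu0 and i by count-weighted linear regression of level mean against
  # level index, which is exact.
  cs <- .clusterStats(hist, mu0, iHat, K)
  if (sum(cs$A > 0) >= 2L && all(cs$sd[cs$A > 0] < 0.5 * bw)) {
    use <- cs$A > 0
    kIdx <- (0:(K - 1L))[use]
    W <- cs$A[use]; y <- cs$m[use]
    Sw <- sum(W); Sk <- sum(W * kIdx); Skk <- sum(W * kIdx^2)
    Sy <- sum(W * y); Sky <- sum(W * kIdx * y)
    denom <- Sw * Skk - Sk^2
    iFit <- (Sw * Sky - Sk * Sy) / denom
    mu0Fit <- (Sy - iFit * Sk) / Sw
    sig <- pmax(cs$sd, bw / sqrt(2 * pi))
    par <- c(mu0Fit, iFit, if (sharedSigma) max(sig) else sig, cs$A)
    fitted <- .gmmModel(par, ctr, bw, K, sharedSigma)
    ssRes <- sum((counts - fitted)^2)
    ssTot <- sum((counts - mean(counts))^2)
    return(new("GmmFit", mu0 = mu0Fit, unitaryAmplitude = iFit,
               sigmas = if (sharedSigma) rep(max(sig), K) else sig,
               weights = cs$A,
               rSquared = if (ssTot > 0) 1 - ssRes / ssTot else
                 as.numeric(ssRes == 0),
               residuals = counts - fitted, fitted = fitted,
               converged = TRUE,
               message = "degenerate histogram: analytic moment fit"))
  }

  ini <- .initComponents(hist, mu0, iHat, K)
  sig0 <- ini$sigma
  nSig <- if (sharedSigma) 1L else K
  lower <- c(-Inf, -Inf, rep(bw / 5, nSig), rep(0, K))
  upper <- c(Inf, Inf, rep(abs(iHat), nSig), rep(Inf, K))

  # fixed jitter sequence: deterministic restarts, no RNG state touched
  jit <- rbind(c(0, 0), c(1, 0.02), c(-1, -0.02), c(2, 0.05), c(-2, -0.05),
               c(0.5, 0.1))
  best <- NULL
  for (r in seq_len(min(maxRestarts + 1L, nrow(jit)))) {
    par0 <- c(mu0 + jit[r, 1L] * bw, iHat * (1 + jit[r, 2L]),
              rep(min(sig0, abs(iHat) * 0.9), nSig), pmax(ini$A, 0))
    fn <- function(p) counts - .gmmModel(p, ctr, bw, K, sharedSigma)
    fit <- try(minpack.lm::nls.lm(
      par = par0, fn = fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss)
      best <- list(fit = fit, ss = ss, conv = fit$info %in% 1:3)
    if (best$conv && r == 1L) break
  }
  if (is.null(best))
    stop("fit error: Gaussian mixture optimization failed on all restarts")
  if (!best$conv)
    warning("constrained GMM fit did not converge; returning best attempt")
  p <- best$fit$par
  sig <- if (sharedSigma) rep(p[3L], K) else p[3L:(2L + K)]
  A <- if (sharedSigma) p[4L:(3L + K)] else p[(3L + K):(2L + 2L * K)]
  fitted <- .gmmModel(p, ctr, bw, K, sharedSigma)
  ssRes <- sum((counts - fitted)^2)
  ssTot <- sum((counts - mean(counts))^2)
  new("GmmFit", mu0 = p[1L], unitaryAmplitude = p[2L], sigmas = sig,
      weights = A,
      rSquared = if (ssTot > 0) 1 - ssRes / ssTot else as.numeric(ssRes == 0),
      residuals = counts - fitted, fitted = fitted,
      converged = best$conv, message = best$fit$message)
}
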