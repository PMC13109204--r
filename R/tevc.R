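# Whole-cell (TEVC) layer: amiloride-sensitive current fractions, protease
# fold change, and the MTSET degenerin-site relative-activity estimator.

.epochMean <- function(trace, from, to) {
  t <- trace@startTime + (seq_along(trace@samples) - 1L) / trace@samplingRate
  sel <- t >= from & t < to
  if (!any(sel)) return(NA_real_)
  mean(trace@samples[sel])
}

#' Amiloride-sensitive current fractions
#'
#' For each \code{amiloride} epoch, computes the amiloride-sensitive current
#' as the difference between the plateau current immediately before the
#' application and the current during the block:
#' the mean over the trailing \code{window} seconds of the preceding
#' non-amiloride epoch minus the mean over the trailing \code{window}
#' seconds of the amiloride epoch. The magnitude is reported in
#' \code{delta}; the signed difference is kept in \code{signedDelta}
#' (negative for inward ENaC current: before minus during < 0 ... > 0
#' depends on the sign convention, which is recorded as-is). Trailing
#' windows avoid solution-exchange transients at epoch starts. An amiloride
#' epoch with no preceding reference plateau is skipped with a warning.
#'
#' @param trace a [Trace-class] (whole-cell current).
#' @param epochs an [EpochSet-class] covering the protocol.
#' @param window plateau window in seconds (default 5; clipped with a
#'   warning if an epoch is shorter).
#' @return data.frame with one row per usable amiloride epoch: columns
#'   \code{amiStart}, \code{amiEnd}, \code{refLabel}, \code{meanBefore},
#'   \code{meanDuring}, \code{signedDelta}, \code{delta}.
#' @examples
#' ep <- makeTevcEpochs("protease")
#' sim <- simulateTevcTrace(tevcSimConfig(ep, pOpenBaseline = 0.3,
#'   proteasePoMultiplier = 2.88, seed = 1))
#' deltaIAmi(simTrace(sim), epochs(sim))
#' @export
deltaIAmi <- function(trace, epochs, window = 5) {
  stopifnot(is(trace, "Trace"), is(epochs, "EpochSet"))
  if (!is.finite(window) || window <= 0)
    stop("window must be a positive duration in seconds")
  ep <- epochs@epochs
  ami <- ep[ep$label == "amiloride", , drop = FALSE]
  if (nrow(ami) == 0L)
    stop("input error: no amiloride epoch in the epoch set")
  other <- ep[ep$label != "amiloride", , drop = FALSE]
  rows <- list()
  for (j in seq_len(nrow(ami))) {
    prev <- other[other$end <= ami$start[j] + 1e-9, , drop = FALSE]
    if (nrow(prev) == 0L) {
      warning("amiloride epoch at ", ami$start[j],
              " s has no preceding reference plateau; skipped")
      next
    }
    ref <- prev[which.max(prev$end), , drop = FALSE]
    wRef <- min(window, ref$end - ref$start)
    wAmi <- min(window, ami$end[j] - ami$start[j])
    if (wRef < window || wAmi < window)
      warning("plateau window clipped to epoch length")
    before <- .epochMean(trace, ref$end - wRef, ref$end)
    during <- .epochMean(trace, ami$end[j] - wAmi, ami$end[j])
    rows[[length(rows) + 1L]] <- data.frame(
      amiStart = ami$start[j], amiEnd = ami$end[j], refLabel = ref$label,
      meanBefore = before, meanDuring = during,
      signedDelta = before - during, delta = abs(before - during))
  }
  if (!length(rows))
    stop("input error: no amiloride epoch had a usable reference plateau")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold change in amiloride-sensitive current
#'
#' Channel activity after a treatment (protease, mock incubation) relative
#' to before, measured as the ratio of amiloride-sensitive currents. Note
#' that whole-cell run-down is not corrected: treated groups are compared
#' against mock-treated controls, whose fold change falls below 1 as the
#' current runs down.
#'
#' @param before amiloride-sensitive current before treatment (> 0).
#' @param after amiloride-sensitive current after treatment.
#' @param noiseFloor values of \code{before} at or below this are considered
#'   indistinguishable from noise; the fold change is then NA with a
#'   warning. Default 0.
#' @return \code{after / before} (dimensionless).
#' @examples
#' foldChange(4, 8)   # 2
#' @export
foldChange <- function(before, after, noiseFloor = 0) {
  if (!is.finite(before) || before <= noiseFloor) {
    warning("fold change undefined: reference current at or below the ",
            "noise floor")
    return(NA_real_)
  }
  after / before
}

#' Relative channel activity from MTSET modification
#'
#' For channels carrying an engineered degenerin-site cysteine, MTSET locks
#' the open probability near 1 without (by assumption) changing the unitary
#' conductance. The ratio of the amiloride-sensitive current before MTSET to
#' that after MTSET then estimates the baseline open probability of the
#' channel population. Values above 1 (more current before than after
#' activation) are reported with a warning since they contradict the
#' activation assumption.
#'
#' @param before amiloride-sensitive current before MTSET.
#' @param after amiloride-sensitive current after MTSET (> 0).
#' @return \code{before / after} (dimensionless, expected in [0, 1]).
#' @examples
#' relativeActivity(9.4, 10)   # 0.94
#' @export
relativeActivity <- function(before, after) {
  if (!is.finite(after) || after <= 0)
    stop("relative activity undefined: post-MTSET current must be > 0")
  r <- before / after
  if (is.finite(r) && r > 1 + 1e-12)
    warning("relative activity > 1: current decreased after MTSET")
  r
}

#' Group summary: mean, SD, n
#'
#' @param values numeric vector (n >= 1).
#' @return A one-row data.frame with \code{mean}, \code{sd} (sample SD,
#'   n - 1 denominator; NA for n = 1) and \code{n}.
#' @examples
#' summarizeGroup(c(0, 2))   # mean 1, sd 1.414, n 2
#' @export
summarizeGroup <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("at least one value is required")
  data.frame(mean = mean(values), sd = stats::sd(values),
             n = length(values))
}

#' Analyze an epoch-annotated whole-cell recording
#'
#' Computes all amiloride-sensitive current fractions and, when at least two
#' amiloride applications are present, the fold change (second / first;
#' protease protocols) and the relative activity (first / second; MTSET
#' protocols) between the first two.
#'
#' @param trace a [Trace-class].
#' @param epochs an [EpochSet-class].
#' @param window plateau window in seconds (default 5).
#' @return A [TevcResult-class].
#' @export
analyzeTevc <- function(trace, epochs, window = 5) {
  flags <- character(0)
  d <- withCallingHandlers(
    deltaIAmi(trace, epochs, window = window),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  fc <- NA_real_; ra <- NA_real_
  if (nrow(d) >= 2L) {
    fc <- withCallingHandlers(
      foldChange(d$delta[1L], d$delta[2L]),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    if (d$delta[2L] > 0)
      ra <- withCallingHandlers(
        relativeActivity(d$delta[1L], d$delta[2L]),
        warning = function(w) {
          flags <<- c(flags, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    else flags <- c(flags, "relative activity undefined (no post current)")
  } else {
    flags <- c(flags, "fewer than two amiloride applications")
  }
  new("TevcResult", deltaIAmi = d, foldChange = fc, relativeActivity = ra,
      flags = flags)
}
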