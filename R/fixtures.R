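# Deterministic fixture bundles: one low-Po multi-channel patch, one
# high-Po single-level patch, and paired whole-cell protease / MTSET traces.

#' Generate a reproducible fixture bundle
#'
#' Writes four synthetic recordings to \code{outDir}: a multi-channel patch
#' with six low-open-probability channels (alpha-beta-gamma-like: seven
#' equidistant current levels), a patch showing only two current levels with
#' a high open probability (delta-beta-gamma-like), a whole-cell protease
#' protocol trace and a whole-cell MTSET protocol trace, each with its JSON
#' sidecar and epoch file, plus a manifest with configurations and MD5
#' checksums. The same seed yields a byte-identical bundle.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; per-file seeds are derived as seed + 0..3.
#' @param patchDuration patch recording length in seconds (default 60).
#' @return Invisibly, the manifest list.
#' @export
makeFixtures <- function(outDir, seed, patchDuration = 60) {
  if (missing(seed)) stop("a seed is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  cfgA <- patchSimConfig(nChannels = 6, pOpen = 0.34,
                         unitaryAmplitude = -0.35, noiseSd = 0.05,
                         duration = patchDuration, seed = seed)
  cfgD <- patchSimConfig(nChannels = 1, pOpen = 0.8,
                         unitaryAmplitude = -0.32, noiseSd = 0.05,
                         duration = patchDuration, seed = seed + 1L)
  simA <- simulatePatchTrace(cfgA)
  simD <- simulatePatchTrace(cfgD)
  writeTrace(simA@trace, file.path(outDir, "abg-patch.csv"))
  writeTrace(simD@trace, file.path(outDir, "dbg-patch.csv"))

  epP <- makeTevcEpochs("protease")
  cfgP <- tevcSimConfig(epP, pOpenBaseline = 0.3,
                        proteasePoMultiplier = 2.88, rundownRate = 0,
                        noiseSd = 0.02, seed = seed + 2L)
  simP <- simulateTevcTrace(cfgP)
  writeTrace(simP@trace, file.path(outDir, "tevc-protease.csv"))
  writeEpochs(epP, file.path(outDir, "tevc-protease-epochs.json"))

  epM <- makeTevcEpochs("mtset")
  cfgM <- tevcSimConfig(epM, pOpenBaseline = 0.94, pOpenAfterMtset = 1,
                        rundownRate = 0, noiseSd = 0.02, seed = seed + 3L)
  simM <- simulateTevcTrace(cfgM)
  writeTrace(simM@trace, file.path(outDir, "tevc-mtset.csv"))
  writeEpochs(epM, file.path(outDir, "tevc-mtset-epochs.json"))

  files <- c("abg-patch.csv", "abg-patch.json", "dbg-patch.csv",
             "dbg-patch.json", "tevc-protease.csv", "tevc-protease.json",
             "tevc-protease-epochs.json", "tevc-mtset.csv",
             "tevc-mtset.json", "tevc-mtset-epochs.json")
  manifest <- list(
    seed = seed,
    configs = list(abg_patch = .stripNonScalar(unclass(cfgA)),
                   dbg_patch = .stripNonScalar(unclass(cfgD)),
                   tevc_protease = .stripNonScalar(unclass(cfgP)),
                   tevc_mtset = .stripNonScalar(unclass(cfgM))),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outDir, files))), files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
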