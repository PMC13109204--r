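# Two-state gating simulator: degenerate states, stationarity, determinism.

test_that("absorbing closed and open states produce constant traces", {
  simClosed <- simulatePatchTrace(patchSimConfig(
    nChannels = 3, pOpen = 0, noiseSd = 0, filterCutoff = NULL,
    baselineCurrent = -0.1, duration = 1, seed = 7))
  expect_true(all(openCount(simClosed) == 0L))
  expect_equal(unique(samples(simTrace(simClosed))), -0.1)

  simOpen <- simulatePatchTrace(patchSimConfig(
    nChannels = 2, pOpen = 1, noiseSd = 0, filterCutoff = NULL,
    unitaryAmplitude = -0.32, baselineCurrent = 0.05, duration = 1,
    seed = 7))
  expect_true(all(openCount(simOpen) == 2L))
  expect_equal(unique(samples(simTrace(simOpen))), 0.05 + 2 * -0.32)
})

test_that("fraction of samples with any channel open matches independence", {
  # closed form for 6 independent channels at Po = 0.34: 1 - 0.66^6
  sim <- simulatePatchTrace(patchSimConfig(
    nChannels = 6, pOpen = 0.34, duration = 60, seed = 11))
  expect_equal(mean(openCount(sim) > 0L), 1 - (1 - 0.34)^6,
               tolerance = 0.03)
})

test_that("long-run open fraction and dwell times match the configuration", {
  sim <- simulatePatchTrace(patchSimConfig(
    nChannels = 1, pOpen = 0.5, meanOpenDwell = 0.2, noiseSd = 0,
    filterCutoff = NULL, samplingRate = 2000, duration = 300, seed = 3))
  st <- openCount(sim)
  expect_lt(abs(mean(st) - 0.5), 0.05)
  r <- rle(as.integer(st))
  meanOpen <- mean(r$lengths[r$values == 1L]) / 2000
  meanClosed <- mean(r$lengths[r$values == 0L]) / 2000
  expect_lt(abs(meanOpen - 0.2), 0.03)
  expect_lt(abs(meanClosed - 0.2), 0.03)
})

test_that("noiseless unfiltered trace only visits quantized current levels", {
  sim <- simulatePatchTrace(patchSimConfig(
    nChannels = 4, pOpen = 0.4, noiseSd = 0, filterCutoff = NULL,
    unitaryAmplitude = -0.35, baselineCurrent = 0.02, duration = 20,
    seed = 5))
  lv <- sort(unique(samples(simTrace(sim))))
  expect_true(all(vapply(lv, function(v)
    any(abs(v - (0.02 + (0:4) * -0.35)) < 1e-12), logical(1))))
})

test_that("identical seeds give bit-identical traces", {
  cfg <- patchSimConfig(nChannels = 2, pOpen = 0.3, duration = 5, seed = 42)
  expect_identical(samples(simTrace(simulatePatchTrace(cfg))),
                   samples(simTrace(simulatePatchTrace(cfg))))
})

test_that("invalid patch configurations are rejected", {
  expect_error(patchSimConfig(nChannels = 1, pOpen = 0.5,
                              meanOpenDwell = 0, seed = 1), "dwell")
  expect_error(patchSimConfig(nChannels = 1, pOpen = 0.5, noiseSd = -1,
                              seed = 1), "noiseSd")
  expect_error(patchSimConfig(nChannels = 1, pOpen = 1.5, seed = 1),
               "pOpen")
  expect_error(patchSimConfig(nChannels = 0, pOpen = 0.5, seed = 1),
               "nChannels")
  expect_error(patchSimConfig(nChannels = 1, pOpen = 0.5), "seed")
})

test_that("null protease treatment gives fold change 1", {
  ep <- makeTevcEpochs("protease")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.4, proteasePoMultiplier = 1, rundownRate = 0,
    noiseSd = 0, seed = 1))
  res <- analyzeTevc(simTrace(sim), epochs(sim))
  expect_equal(slot(res, "foldChange"), 1.0)
})

test_that("MTSET doubling: Po 0.5 -> 1.0 doubles the blocked current", {
  ep <- makeTevcEpochs("mtset")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.5, pOpenAfterMtset = 1, noiseSd = 0, seed = 1))
  d <- deltaIAmi(simTrace(sim), epochs(sim))
  expect_equal(d$delta[2L], 2 * d$delta[1L])
})

test_that("run-down alone pushes the control fold change below 1", {
  ep <- makeTevcEpochs("protease")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.4, proteasePoMultiplier = 1, rundownRate = 0.03,
    noiseSd = 0, seed = 1))
  res <- analyzeTevc(simTrace(sim), epochs(sim))
  fc <- slot(res, "foldChange")
  expect_lt(fc, 1)
  # plateaus sit ~450 s apart; decay factor (1 - r)^(dt/60)
  expect_equal(fc, (1 - 0.03)^(450 / 60), tolerance = 0.02)
})

test_that("overlapping epochs are rejected by the schedule check", {
  ep <- EpochSet(c("highNa", "amiloride"), start = c(0, 30),
                 end = c(60, 90))
  expect_error(tevcSimConfig(ep, seed = 1), "overlap")
})
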