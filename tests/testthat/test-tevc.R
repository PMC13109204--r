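# Whole-cell estimators: amiloride-sensitive currents, fold change, MTSET.

test_that("amiloride-sensitive current is the plateau difference", {
  ep <- EpochSet(c("highNa", "amiloride"), start = c(0, 60), end = c(60, 90))
  t <- seq(0, 90 - 1 / 20, by = 1 / 20)
  cur <- ifelse(t < 60, -5, -1)
  tr <- Trace(cur, samplingRate = 20, units = "uA")
  d <- deltaIAmi(tr, ep)
  expect_equal(nrow(d), 1L)
  expect_equal(d$delta, 4)
  expect_equal(d$meanBefore, -5)
  expect_equal(d$meanDuring, -1)
})

test_that("zero channel activity gives a null amiloride response", {
  ep <- makeTevcEpochs("protease")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, nChannels = 0, leakCurrent = -0.5, noiseSd = 0.01, seed = 2))
  d <- deltaIAmi(simTrace(sim), epochs(sim))
  expect_true(all(abs(d$delta) < 0.01))
})

test_that("run-down makes the second amiloride response smaller", {
  ep <- makeTevcEpochs("protease")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.4, proteasePoMultiplier = 1, rundownRate = 0.05,
    noiseSd = 0, seed = 3))
  d <- deltaIAmi(simTrace(sim), epochs(sim))
  expect_lt(d$delta[2L], d$delta[1L])
})

test_that("an amiloride epoch at the trace start is skipped with a warning", {
  ep <- EpochSet(c("amiloride", "highNa", "amiloride"),
                 start = c(0, 30, 90), end = c(30, 90, 120))
  t <- seq(0, 120 - 1 / 20, by = 1 / 20)
  tr <- Trace(ifelse(t >= 30 & t < 90, -5, -1), samplingRate = 20,
              units = "uA")
  expect_warning(d <- deltaIAmi(tr, ep), "no preceding reference")
  expect_equal(nrow(d), 1L)
})

test_that("fold change and relative activity are the declared ratios", {
  expect_equal(foldChange(4, 8), 2.0)
  expect_equal(foldChange(4, 4), 1.0)
  expect_warning(fc <- foldChange(0, 5), "noise floor")
  expect_true(is.na(fc))
  expect_equal(relativeActivity(9.4, 10), 0.94)
  expect_equal(relativeActivity(7, 7), 1.0)
  expect_error(relativeActivity(5, 0), "must be > 0")
  expect_warning(relativeActivity(8, 5), "> 1")
})

test_that("protease activation tuned to a macroscopic ratio is recovered", {
  ep <- makeTevcEpochs("protease")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.3, proteasePoMultiplier = 2.88, rundownRate = 0,
    noiseSd = 0.005, seed = 4))
  res <- analyzeTevc(simTrace(sim), epochs(sim))
  expect_equal(slot(res, "foldChange"), 2.88, tolerance = 0.02)
})

test_that("noise-free MTSET simulation returns the baseline Po exactly", {
  ep <- makeTevcEpochs("mtset")
  sim <- simulateTevcTrace(tevcSimConfig(
    ep, pOpenBaseline = 0.67, pOpenAfterMtset = 1, noiseSd = 0,
    rundownRate = 0, seed = 5))
  res <- analyzeTevc(simTrace(sim), epochs(sim))
  expect_equal(slot(res, "relativeActivity"), 0.67)
})

test_that("fold change is invariant to the unitary-current scale", {
  ep <- makeTevcEpochs("protease")
  fcs <- vapply(c(-5e-6, -2e-5), function(i0) {
    sim <- simulateTevcTrace(tevcSimConfig(
      ep, unitaryCurrent = i0, pOpenBaseline = 0.3,
      proteasePoMultiplier = 2, noiseSd = 0, seed = 6))
    slot(analyzeTevc(simTrace(sim), epochs(sim)), "foldChange")
  }, numeric(1))
  expect_equal(fcs[1L], fcs[2L])
})

test_that("amiloride-sensitive current ignores a constant leak", {
  ep <- makeTevcEpochs("mtset")
  ds <- lapply(c(0, -3), function(leak) {
    sim <- simulateTevcTrace(tevcSimConfig(
      ep, pOpenBaseline = 0.5, leakCurrent = leak, noiseSd = 0, seed = 7))
    deltaIAmi(simTrace(sim), epochs(sim))$delta
  })
  expect_equal(ds[[1L]], ds[[2L]])
})

test_that("group summaries report mean, sample SD and n", {
  expect_equal(summarizeGroup(c(1, 1, 1)),
               data.frame(mean = 1, sd = 0, n = 3L))
  s <- summarizeGroup(c(0, 2))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$n, 2L)
  expect_error(summarizeGroup(numeric(0)), "at least one")
})
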