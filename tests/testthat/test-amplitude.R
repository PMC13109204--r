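# Amplitude histograms, level detection, constrained Gaussian mixture.

test_that("constant trace yields a single fully loaded bin", {
  h <- buildAmplitudeHistogram(rep(-0.5, 1000))
  expect_equal(sum(binCounts(h) > 0), 1L)
  expect_equal(sum(binCounts(h)), 1000)
})

test_that("default bin width is 0.01 and counts conserve samples", {
  sim <- quickPatch(n = 1, po = 0.5, duration = 2, seed = 9)
  h <- buildAmplitudeHistogram(simTrace(sim))
  expect_equal(binWidth(h), 0.01)
  expect_equal(sum(binCounts(h)), length(samples(simTrace(sim))))
  expect_error(buildAmplitudeHistogram(numeric(0)), "empty")
  expect_error(buildAmplitudeHistogram(1:3, binWidth = 0), "binWidth")
})

test_that("pure Gaussian noise is consistent with one Gaussian (chi-square GOF)", {
  set.seed(4)
  x <- rnorm(1e5, mean = -0.2, sd = 0.05)
  h <- buildAmplitudeHistogram(x, binWidth = 0.01)
  br <- slot(h, "breaks")
  pr <- diff(pnorm(br, mean = -0.2, sd = 0.05))
  pr[1L] <- pr[1L] + pnorm(br[1L], -0.2, 0.05)
  pr[length(pr)] <- pr[length(pr)] + pnorm(br[length(br)], -0.2, 0.05,
                                           lower.tail = FALSE)
  expected <- 1e5 * pr
  keep <- expected >= 5
  obs <- c(binCounts(h)[keep], sum(binCounts(h)[!keep]))
  exp <- c(expected[keep], sum(expected[!keep]))
  stat <- sum((obs - exp)^2 / exp)
  p <- pchisq(stat, df = length(obs) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("level detection counts the observable current levels", {
  sim6 <- simulatePatchTrace(patchSimConfig(
    nChannels = 6, pOpen = 0.34, duration = 60, seed = 1))
  det6 <- detectLevels(buildAmplitudeHistogram(simTrace(sim6)))
  expect_equal(det6$nLevels, 7L)
  expect_equal(det6$i, -0.35, tolerance = 0.05)

  sim1 <- quickPatch(n = 1, po = 0.8, duration = 10, seed = 2)
  det1 <- detectLevels(buildAmplitudeHistogram(simTrace(sim1)))
  expect_equal(det1$nLevels, 2L)

  set.seed(8)
  flat <- detectLevels(buildAmplitudeHistogram(rnorm(1e4, sd = 0.05)))
  expect_equal(flat$nLevels, 1L)
  expect_equal(flat$i, 0)
})

test_that("noiseless two-level histogram is recovered exactly", {
  x <- c(rep(0, 3000), rep(-0.32, 7000))
  fit <- fitConstrainedGmm(buildAmplitudeHistogram(x), nComponents = 2)
  expect_equal(baselineMean(fit), 0, tolerance = 1e-6)
  expect_equal(unitaryAmplitude(fit), -0.32, tolerance = 1e-6)
  expect_equal(componentWeights(fit)[1] / sum(componentWeights(fit)), 0.3,
               tolerance = 1e-6)
})

test_that("unitary amplitude is recovered within 0.02 pA on a noisy channel", {
  sim <- simulatePatchTrace(patchSimConfig(
    nChannels = 1, pOpen = 0.8, unitaryAmplitude = -0.32, noiseSd = 0.05,
    duration = 60, seed = 6))
  fit <- fitConstrainedGmm(buildAmplitudeHistogram(simTrace(sim)))
  expect_equal(unitaryAmplitude(fit), -0.32, tolerance = 0.02)
})

test_that("component weights conserve the sample count on separated levels", {
  # unfiltered: every sample sits at a level, none are smeared mid-transition
  sim <- simulatePatchTrace(patchSimConfig(
    nChannels = 1, pOpen = 0.8, unitaryAmplitude = -0.32, noiseSd = 0.05,
    filterCutoff = NULL, duration = 60, seed = 6))
  fit <- fitConstrainedGmm(buildAmplitudeHistogram(simTrace(sim)))
  expect_equal(sum(componentWeights(fit)),
               length(samples(simTrace(sim))), tolerance = 0.01)
})

test_that("fit is invariant to adding a constant to all samples", {
  sim <- quickPatch(n = 2, po = 0.4, duration = 10, seed = 12)
  x <- samples(simTrace(sim))
  f0 <- fitConstrainedGmm(buildAmplitudeHistogram(x), nComponents = 3)
  f1 <- fitConstrainedGmm(buildAmplitudeHistogram(x + 1.5), nComponents = 3)
  expect_equal(baselineMean(f1) - baselineMean(f0), 1.5, tolerance = 1e-8)
  expect_equal(unitaryAmplitude(f1), unitaryAmplitude(f0), tolerance = 1e-8)
  expect_equal(componentWeights(f1), componentWeights(f0),
               tolerance = 1e-6)
})

test_that("increasing the component count never worsens the fit", {
  sim <- quickPatch(n = 2, po = 0.4, duration = 10, seed = 13)
  h <- buildAmplitudeHistogram(simTrace(sim))
  r2 <- vapply(3:5, function(k)
    rSquared(fitConstrainedGmm(h, nComponents = k)), numeric(1))
  expect_true(all(diff(r2) >= -1e-6))
})

test_that("shared-sigma mode fits one common component width", {
  sim <- quickPatch(n = 1, po = 0.6, duration = 10, seed = 14)
  fit <- fitConstrainedGmm(buildAmplitudeHistogram(simTrace(sim)),
                           sharedSigma = TRUE)
  expect_equal(length(unique(componentSigmas(fit))), 1L)
  expect_equal(unitaryAmplitude(fit), -0.35, tolerance = 0.02)
})
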