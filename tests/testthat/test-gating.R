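# Occupation probabilities, binomial fitting, channel-count scanning.

test_that("occupation probabilities normalize the component weights", {
  expect_equal(occupancies(occupationProbabilities(c(100, 0))), c(1, 0))
  expect_equal(occupancies(occupationProbabilities(c(20, 80))), c(0.2, 0.8))
  expect_equal(occupancies(occupationProbabilities(c(1, 1, 2))),
               c(0.25, 0.25, 0.5))
  expect_error(occupationProbabilities(c(0, 0)), "zero")
  # normalization invariant over random profiles
  set.seed(2)
  for (r in 1:50) {
    w <- runif(sample(2:8, 1), 0, 100)
    expect_lt(abs(sum(occupancies(occupationProbabilities(w))) - 1), 1e-9)
  }
})

test_that("two-level profile at N = 1 gives Po = 0.8 with perfect fit", {
  fit <- fitBinomialPo(c(0.2, 0.8), nChannels = 1)
  expect_equal(pOpen(fit), 0.8)
  expect_equal(rSquared(fit), 1)
})

test_that("symmetric three-level profile at N = 2 gives Po = 0.5 exactly", {
  fit <- fitBinomialPo(c(0.25, 0.5, 0.25), nChannels = 2)
  expect_equal(pOpen(fit), 0.5, tolerance = 1e-8)
  expect_equal(rSquared(fit), 1, tolerance = 1e-12)
})

test_that("top-open fit with an unobserved middle level matches the grid oracle", {
  occ <- occupationProbabilities(c(20, 80), anchoring = "top_open")
  fit <- fitBinomialPo(occ, nChannels = 2)
  expect_equal(slot(fit, "levelMap"), c(0L, 2L))
  # frozen value from an exhaustive grid (step 1e-5) over the declared
  # least-squares objective with the unobserved k = 1 penalized against 0
  expect_equal(pOpen(fit), 0.94296, tolerance = 1e-4)
  # observed-levels-only variant fits just k = 0 and k = 2
  fitObs <- fitBinomialPo(occ, nChannels = 2, objective = "observed_only")
  expect_equal(pOpen(fitObs), 0.88019, tolerance = 1e-4)
})

test_that("fitted Po agrees with the exhaustive grid on random profiles", {
  set.seed(5)
  for (r in 1:20) {
    K <- sample(2:5, 1)
    w <- runif(K, 0.01, 1)
    anch <- sample(c("baseline_closed", "top_open"), 1)
    occ <- occupationProbabilities(w, anchoring = anch)
    N <- K - 1L + sample(0:2, 1)
    fit <- fitBinomialPo(occ, N)
    oracle <- gridOraclePo(slot(fit, "observed"), 0:N, N)
    expect_equal(pOpen(fit), oracle, tolerance = 1e-4)
  }
})

test_that("scanning N moves Po in the direction set by the anchoring", {
  # high-Po two-level profile, all channels open at the top level
  sc <- scanChannelCount(
    occupationProbabilities(c(20, 80), anchoring = "top_open"), nMax = 3)
  expect_true(all(diff(sc$pOpen) > 0))
  # multi-level low-Po profile, baseline closed
  occ <- occupationProbabilities(dbinom(0:6, 6, 0.34))
  sc2 <- scanChannelCount(occ, nMin = 6, nMax = 8)
  expect_true(all(diff(sc2$pOpen) <= 1e-12))
})

test_that("an exactly binomial profile is best explained at the true N", {
  occ <- occupationProbabilities(dbinom(0:4, 4, 0.3))
  sc <- scanChannelCount(occ, nMin = 4, nMax = 7)
  expect_equal(bestChannelCount(sc), 4)
  expect_equal(sc$rSquared[1L], 1, tolerance = 1e-10)
  expect_equal(sc$pOpen[1L], 0.3, tolerance = 1e-6)
})

test_that("N below the observed open levels is a mapping error", {
  expect_error(fitBinomialPo(c(0.1, 0.4, 0.5), nChannels = 1), "mapping")
})

test_that("full pipeline recovers Po on simulated patches", {
  sim1 <- quickPatch(n = 1, po = 0.8, duration = 30, seed = 21)
  est1 <- estimatePoFromTrace(simTrace(sim1))
  expect_equal(pOpen(est1), 0.8, tolerance = 0.05)
  expect_equal(nChannels(est1), 1L)

  set.seed(31)
  silent <- estimatePoFromTrace(rnorm(2e4, sd = 0.05))
  expect_equal(pOpen(silent), 0)
  expect_true("no open levels detected" %in% slot(silent, "flags"))
})

test_that("pipeline report serializes all intermediates", {
  d <- withr::local_tempdir()
  est <- estimatePoFromTrace(simTrace(quickPatch(duration = 5, seed = 22)))
  p <- file.path(d, "est.json")
  writeReport(list(estimate = est), p)
  rep <- readReport(p)
  expect_equal(rep$results$estimate$p_open, pOpen(est))
  expect_false(is.null(rep$results$estimate$gmm))
  expect_false(is.null(rep$results$estimate$occupancy))
})
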