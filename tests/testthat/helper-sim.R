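# Shared simulation helpers for the test suite.

quickPatch <- function(n = 1, po = 0.8, duration = 10, seed = 1, ...) {
  simulatePatchTrace(patchSimConfig(nChannels = n, pOpen = po,
                                    duration = duration, seed = seed, ...))
}

# Memoized runs at the six-channel low-Po operating point (60 s recordings,
# ten seeds); shared between the recovery and amplitude acceptance checks so
# the simulations are only generated once per test run.
.accEnv <- new.env(parent = emptyenv())

lowPoRuns <- function() {
  if (is.null(.accEnv$runs)) {
    .accEnv$runs <- lapply(1:10, function(s) {
      sim <- simulatePatchTrace(patchSimConfig(
        nChannels = 6, pOpen = 0.34, unitaryAmplitude = -0.35,
        noiseSd = 0.05, samplingRate = 10000, filterCutoff = 100,
        duration = 60, seed = s))
      estimatePoFromTrace(simTrace(sim), nChannels = 6)
    })
  }
  .accEnv$runs
}

# brute-force grid oracle for the binomial least-squares objective
gridOraclePo <- function(obs, useK, N, step = 1e-5) {
  p <- seq(0, 1, by = step)
  pred <- vapply(useK, function(k) dbinom(k, N, p), numeric(length(p)))
  sse <- rowSums(sweep(pred, 2L, obs[useK + 1L])^2)
  p[which.min(sse)]
}
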