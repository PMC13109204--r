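# Trace, epoch and report I/O: round trips, dialects, validation.

test_that("a small CSV with sidecar parses to a Trace", {
  d <- withr::local_tempdir()
  p <- file.path(d, "t.csv")
  writeLines(c("0,-1.0", "0.0001,-1.3", "0.0002,-1.0"), p)
  jsonlite::write_json(list(units = "pA", sampling_rate = 10000),
                       file.path(d, "t.json"), auto_unbox = TRUE)
  tr <- readTrace(p)
  expect_s4_class(tr, "Trace")
  expect_length(samples(tr), 3)
  expect_equal(samples(tr), c(-1.0, -1.3, -1.0))
  expect_equal(samplingRate(tr), 10000)
  expect_equal(traceUnits(tr), "pA")
})

test_that("write/read round trip reproduces samples exactly", {
  d <- withr::local_tempdir()
  set.seed(1)
  tr <- Trace(rnorm(500, sd = 0.05) + pi * 1e-3, samplingRate = 10000,
              units = "pA", channelLabel = "rt", startTime = 0.25)
  p <- file.path(d, "rt.csv")
  writeTrace(tr, p)
  tr2 <- readTrace(p)
  expect_identical(samples(tr2), samples(tr))
  expect_equal(samplingRate(tr2), samplingRate(tr))
  expect_equal(traceUnits(tr2), "pA")
  expect_equal(startTime(tr2), 0.25)
})

test_that("ATF dialect yields the same samples as the equivalent CSV", {
  d <- withr::local_tempdir()
  cur <- c(-1.0, -1.3, -1.05, -0.98)
  tt <- (0:3) / 1000
  atf <- file.path(d, "t.atf")
  writeLines(c(
    "ATF\t1.0", "2\t2",
    "\"AcquisitionMode=synthetic\"", "\"Comment=\"",
    "\"Time (s)\"\t\"Current (pA)\"",
    sprintf("%g\t%g", tt, cur)), atf)
  trA <- readTrace(atf, dialect = "atf")
  expect_equal(samples(trA), cur)
  expect_equal(traceUnits(trA), "pA")
  expect_equal(samplingRate(trA), 1000)

  csv <- file.path(d, "t2.csv")
  writeLines(sprintf("%g,%g", tt, cur), csv)
  trC <- readTrace(csv, units = "pA")
  expect_equal(samples(trC), samples(trA))
})

test_that("metadata and format errors are raised", {
  d <- withr::local_tempdir()
  p <- file.path(d, "nounits.csv")
  writeLines(c("0,-1", "0.1,-2"), p)
  expect_error(readTrace(p), "units")
  q <- file.path(d, "nonuniform.csv")
  writeLines(c("0,-1", "0.1,-2", "0.15,-1"), q)
  expect_error(readTrace(q, units = "pA"), "non-uniform")
  expect_error(readTrace(file.path(d, "absent.csv")), "no such file")
})

test_that("epoch files round-trip, empty sets are valid, overlaps rejected", {
  d <- withr::local_tempdir()
  ep <- makeTevcEpochs("mtset")
  p <- file.path(d, "ep.json")
  writeEpochs(ep, p)
  ep2 <- readEpochs(p)
  expect_equal(epochs(ep2), epochs(ep))

  e <- file.path(d, "empty.json")
  writeLines("[]", e)
  expect_equal(nrow(epochs(readEpochs(e))), 0L)

  o <- file.path(d, "bad.json")
  jsonlite::write_json(data.frame(label = c("highNa", "highNa"),
                                  start = c(0, 30), end = c(60, 90)), o)
  expect_error(readEpochs(o), "overlap")
})

test_that("a binomial fit survives a report round trip", {
  d <- withr::local_tempdir()
  fit <- fitBinomialPo(c(0.2, 0.8), nChannels = 1)
  p <- file.path(d, "report.json")
  writeReport(list(binomial = fit), p, config = list(bin_width = 0.01),
              seed = 99)
  rep <- readReport(p)
  expect_equal(rep$results$binomial$n_channels, 1)
  expect_equal(rep$results$binomial$p_open, pOpen(fit))
  expect_equal(rep$results$binomial$r_squared, rSquared(fit))
  expect_equal(rep$seed, 99)
  expect_true(nzchar(rep$config_md5))
})

test_that("scan tables are written as TSV alongside the report", {
  d <- withr::local_tempdir()
  sc <- scanChannelCount(c(0.2, 0.8), nMax = 3)
  p <- file.path(d, "scan.json")
  writeReport(list(scan = sc), p)
  tsv <- file.path(d, "scan-scan.tsv")
  expect_true(file.exists(tsv))
  back <- read.delim(tsv)
  expect_equal(back$N, 1:3)
  expect_equal(back$pOpen, sc$pOpen)
})
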