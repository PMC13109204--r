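# Open-format trace I/O: two-column delimited text (time_s, current) with a
# JSON metadata sidecar, plus read-only support for the Axon Text File (ATF)
# dialect. Proprietary binaries (HEKA .dat, ABF) are out of scope.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.checkUniform <- function(tt, rate) {
  if (length(tt) < 2L) return(invisible(TRUE))
  dt <- 1 / rate
  if (max(abs(diff(tt) - dt)) > 1e-6 * dt)
    stop("format error: non-uniform timebase (time deltas deviate from 1/samplingRate)")
  invisible(TRUE)
}

#' Read a time--current trace
#'
#' Reads a two-column delimited text file (time in seconds, current) in one
#' of two dialects: \code{"csv2col"} (comma-, tab- or whitespace-separated,
#' no header or a non-numeric header line) or \code{"atf"} (Axon Text File,
#' read-only). Units and sampling rate come from the JSON sidecar
#' (\code{<path-without-ext>.json}) when present, otherwise from the
#' \code{units} argument and the time column. Sampling uniformity is
#' verified: the maximum deviation of time deltas must be below 1e-6 of the
#' sampling interval.
#'
#' @param path file to read.
#' @param dialect \code{"csv2col"} (default) or \code{"atf"}.
#' @param units fallback units when no sidecar is present; an error is
#'   raised when units can be determined from neither (metadata error).
#' @return A [Trace-class].
#' @seealso [writeTrace()], [readEpochs()]
#' @export
readTrace <- function(path, dialect = c("csv2col", "atf"), units = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("I/O error: no such file: %s", path))
  meta <- list()
  sc <- .sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::fromJSON(sc, simplifyVector = TRUE)

  if (dialect == "csv2col") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    skip <- if (suppressWarnings(is.na(as.numeric(
      strsplit(first, if (sep == ",") "," else "[ \t]+")[[1L]][1L])))) 1L else 0L
    d <- utils::read.table(path, sep = sep, skip = skip,
                           col.names = c("time_s", "current"),
                           colClasses = "numeric")
    tt <- d$time_s; cur <- d$current
    colUnits <- NULL
  } else {
    atf <- .readAtf(path)
    tt <- atf$time; cur <- atf$current; colUnits <- atf$units
  }
  if (anyNA(tt) || anyNA(cur))
    stop("format error: non-numeric values in trace file")

  u <- meta$units %||% colUnits %||% units
  if (is.null(u)) stop("metadata error: current units not specified ",
                       "(no sidecar, no header units, no 'units' argument)")
  rate <- meta$sampling_rate %||%
    (if (length(tt) > 1L) 1 / stats::median(diff(tt)) else 1)
  .checkUniform(tt, rate)
  Trace(cur, samplingRate = rate, units = u,
        channelLabel = meta$channel_label %||% "",
        startTime = meta$start_time %||% (if (length(tt)) tt[1L] else 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal ATF reader: "ATF <version>" magic, then "<nHeader> <nCols>", then
# nHeader quoted header records, then one line of column titles, then data.
# Time values are taken as seconds unless the time column title mentions ms.
.readAtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !grepl("^ATF", lines[1L]))
    stop("format error: not an ATF file (missing ATF magic)")
  hdr <- scan(text = lines[2L], quiet = TRUE)
  nHeader <- hdr[1L]
  titleLine <- lines[2L + nHeader + 1L]
  titles <- strsplit(gsub('"', "", titleLine), "\t")[[1L]]
  d <- utils::read.table(text = lines[-seq_len(2L + nHeader + 1L)],
                         sep = "\t", colClasses = "numeric")
  if (ncol(d) < 2L) stop("format error: ATF file has fewer than 2 columns")
  tt <- d[[1L]]
  if (length(titles) >= 1L && grepl("\\(ms\\)", titles[1L])) tt <- tt / 1000
  u <- NULL
  if (length(titles) >= 2L) {
    m <- regmatches(titles[2L], regexpr("\\((pA|nA|uA)\\)", titles[2L]))
    if (length(m)) u <- gsub("[()]", "", m)
  }
  list(time = tt, current = d[[2L]], units = u)
}

#' Write a trace as two-column text plus JSON sidecar
#'
#' Samples are written at full double precision (\code{\%.17g}) so that a
#' write/read round trip reproduces them exactly. The sidecar
#' (\code{<path-without-ext>.json}) records units, sampling rate, channel
#' label and start time.
#'
#' @param trace a [Trace-class].
#' @param path output file (e.g. \code{trace.csv}).
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path, sidecar = TRUE) {
  stopifnot(is(trace, "Trace"))
  tt <- trace@startTime + (seq_along(trace@samples) - 1L) / trace@samplingRate
  lines <- sprintf("%.17g,%.17g", tt, trace@samples)
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("I/O error: cannot write %s", path))
  if (sidecar) {
    jsonlite::write_json(
      list(units = trace@units, sampling_rate = trace@samplingRate,
           channel_label = trace@channelLabel, start_time = trace@startTime),
      .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an epoch annotation file
#'
#' Epochs are stored as a JSON array of objects with fields \code{label},
#' \code{start}, \code{end} and optional \code{scale}. An empty array is a
#' valid empty set; overlapping epochs within a label track are rejected.
#'
#' @param path JSON file.
#' @return An [EpochSet-class].
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file: %s", path))
  d <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(d) == 0L) return(EpochSet())
  EpochSet(d$label, d$start, d$end, d$scale %||% 1)
}

#' Write an epoch annotation file
#'
#' @param epochSet an [EpochSet-class].
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeEpochs <- function(epochSet, path) {
  stopifnot(is(epochSet, "EpochSet"))
  jsonlite::write_json(epochSet@epochs, path, digits = NA)
  invisible(path)
}

#' Write an analysis report (JSON, optionally with TSV tables)
#'
#' Serializes a named list of results (pipeline objects are converted via
#' [asReportList()]) to JSON with provenance: the generating configuration,
#' its MD5 hash, the seed, and the package version. Any result that is a
#' data.frame is additionally written as a TSV table next to the report.
#'
#' @param results named list of results.
#' @param path output JSON file.
#' @param config optional configuration list to embed.
#' @param seed optional seed to record.
#' @param tsv also write data.frame results as TSV files (default TRUE).
#' @return \code{path}, invisibly.
#' @seealso [readReport()]
#' @export
writeReport <- function(results, path, config = NULL, seed = NULL,
                        tsv = TRUE) {
  stopifnot(is.list(results))
  payload <- lapply(results, function(x) if (isS4(x)) asReportList(x) else x)
  cfgHash <- NULL
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf), add = TRUE)
    jsonlite::write_json(.stripNonScalar(config), tf, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    cfgHash <- unname(tools::md5sum(tf))
  }
  report <- list(
    package = "patchPo",
    version = as.character(utils::packageVersion("patchPo")),
    seed = seed, config = .stripNonScalar(config), config_md5 = cfgHash,
    results = payload)
  ok <- try(jsonlite::write_json(report, path, auto_unbox = TRUE,
                                 digits = NA, force = TRUE, null = "null"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("I/O error: cannot write %s", path))
  if (tsv) {
    for (nm in names(payload)) {
      if (is.data.frame(payload[[nm]])) {
        utils::write.table(
          payload[[nm]],
          file.path(dirname(path), paste0(
            tools::file_path_sans_ext(basename(path)), "-", nm, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(path)
}

# drop S4 members (e.g. an EpochSet inside a sim config) for serialization
.stripNonScalar <- function(x) {
  if (is.null(x)) return(NULL)
  lapply(x, function(el) {
    if (isS4(el)) {
      if (is(el, "EpochSet")) el@epochs else class(el)[1L]
    } else el
  })
}

#' Read back an analysis report
#'
#' @param path JSON report written by [writeReport()].
#' @return The report as a plain list.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
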