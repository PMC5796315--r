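# Reading and writing ECG records, annotations, per-beat feature tables and
# summary documents. On-disk formats are stable text: CSV for waveforms
# (one column per channel) with a YAML sidecar carrying rate metadata, CSV
# for tables, JSON for the summary document.

sidecarPath <- function(path) paste0(path, ".yaml")

#' Read an ECG record from a delimited-text file
#'
#' Reads one channel of a CSV/TSV waveform file (one column per channel,
#' optional header row). The sampling rate is resolved from, in order: the
#' `fs` argument, a YAML sidecar (`<path>.yaml`) written by
#' [writeRecord()], or an error. Amplitudes are divided by `gain` and
#' stored as mV; recordings made through a high-gain amplifier should pass
#' its gain here.
#'
#' @param path file to read.
#' @param fs sampling rate (Hz), or `NULL` to use the sidecar.
#' @param channel column index or name (default 1).
#' @param gain acquisition gain to divide out (default 1).
#' @return An [ECGRecord-class].
#' @export
readRecord <- function(path, fs = NULL, channel = 1, gain = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  sc <- sidecarPath(path)
  if (file.exists(sc)) meta <- yaml::read_yaml(sc)
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) stop("sampling rate unresolvable: pass 'fs' or provide ",
                        "a YAML sidecar with an 'fs' field")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("no samples in ", path)
  fields <- strsplit(first, "[,\t]")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.csv(path, header = hasHeader,
                        sep = if (grepl("\t", first)) "\t" else ",")
  if (nrow(df) == 0L) stop("no samples in ", path)
  if (is.character(channel)) {
    if (!channel %in% names(df)) stop("channel '", channel, "' not found")
    col <- df[[channel]]
    chId <- channel
  } else {
    if (channel < 1 || channel > ncol(df))
      stop("channel ", channel, " out of range (file has ", ncol(df),
           " channel(s))")
    col <- df[[channel]]
    chId <- if (hasHeader) names(df)[channel] else paste0("ch", channel)
  }
  col <- suppressWarnings(as.numeric(col))
  if (any(is.na(col))) stop("non-numeric rows in ", path)
  ECGRecord(col / gain, fs = fs, channelId = chId,
            t0 = meta$t0 %||% 0,
            meta = list(source = path, gain = gain))
}

#' Write an ECG record as CSV with a YAML sidecar
#'
#' Samples are written with six decimal places (deterministic bytes for a
#' given record); the sidecar carries `fs`, `t0` and the channel label so
#' [readRecord()] can restore the record without arguments.
#'
#' @param record an [ECGRecord-class].
#' @param path destination CSV path.
#' @param sidecar write the YAML sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
writeRecord <- function(record, path, sidecar = TRUE) {
  stopifnot(is(record, "ECGRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(record@channelId, con)
  writeLines(sprintf("%.6f", ecgSamples(record)), con)
  if (sidecar)
    yaml::write_yaml(list(fs = samplingRate(record), t0 = record@t0,
                          channel = record@channelId),
                     sidecarPath(path))
  invisible(path)
}

#' Write ground-truth annotations as a CSV table
#'
#' One row per (beat, wave) with the true sample index, in a long
#' annotation layout.
#'
#' @param truth an [ECGGroundTruth-class].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  b <- truthBeats(truth)
  long <- do.call(rbind, lapply(c("p", "q", "r", "s", "t"), function(w)
    data.frame(beat = b$beat, wave = toupper(w), sample = b[[w]])))
  long <- long[!is.na(long$sample), ]
  long <- long[order(long$beat, long$sample), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the summary document
#'
#' The summary mirrors the analysis front panel: a run-length table of
#' anomalies per R-R interval range, the heart-rate/HRV block, and an echo
#' of the processing configuration.
#'
#' @param reports data.frame from [diagnoseAnomalies()].
#' @param hrv an `"HRVSummary"` from [computeHRV()].
#' @param config list echoing the processing configuration.
#' @return A list of class `"SummaryDocument"`.
#' @export
buildSummary <- function(reports, hrv, config = list()) {
  doc <- list(anomalies = summarizeAnomalies(reports),
              hrv = unclass(hrv),
              nIntervals = nrow(reports),
              allNormal = all(reports$normal_rhythm),
              config = config)
  class(doc) <- "SummaryDocument"
  doc
}

#' @export
print.SummaryDocument <- function(x, ...) {
  cat(sprintf("ECG summary over %d R-R intervals\n", x$nIntervals))
  if (nrow(x$anomalies) == 0) {
    cat("  Normal rhythm throughout; no anomalies detected.\n")
  } else {
    cat("  R-R intervals  Anomaly/Anomalies\n")
    for (i in seq_len(nrow(x$anomalies)))
      cat(sprintf("  %d-%d  %s\n", x$anomalies$from[i], x$anomalies$to[i],
                  x$anomalies$anomalies[i]))
  }
  invisible(x)
}

writeSummaryJSON <- function(doc, path) {
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Save the four analysis artifacts
#'
#' Writes exactly four files into `dir`: the raw record (`raw.csv`), the
#' filtered record (`filtered.csv`), the per-beat feature table
#' (`beat_features.csv`, one row per R-R interval), and the summary
#' document (`summary.json`, which also carries the sampling rate and
#' configuration echo). Output bytes are deterministic for fixed inputs.
#'
#' @param record the raw [ECGRecord-class].
#' @param filtered the filtered [ECGRecord-class].
#' @param features per-interval feature data.frame (e.g.
#'   [computeIntervals()] merged with [stSegmentStats()]).
#' @param summary a `"SummaryDocument"` from [buildSummary()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeOutputs <- function(record, filtered, features, summary, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  paths <- c(raw = file.path(dir, "raw.csv"),
             filtered = file.path(dir, "filtered.csv"),
             features = file.path(dir, "beat_features.csv"),
             summary = file.path(dir, "summary.json"))
  summary$config$fs <- samplingRate(record)
  writeRecord(record, paths["raw"], sidecar = FALSE)
  writeRecord(filtered, paths["filtered"], sidecar = FALSE)
  writeFeatureTable(features, paths["features"])
  writeSummaryJSON(summary, paths["summary"])
  invisible(paths)
}

writeFeatureTable <- function(features, path) {
  num <- vapply(features, is.numeric, logical(1)) &
    !vapply(features, is.integer, logical(1))
  out <- features
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, sprintf("%.6f", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a synthetic-record specification from YAML
#'
#' Accepts the fields of [synthSpec()] (`fs`, `duration`, `heartRate`,
#' `rrJitterSd`, `seed`), an optional `noise` block with [noiseSpec()]
#' fields, an optional `anomaly` block with a `type`, and an optional
#' `waves` block overriding per-wave `amp`/`width`/`offset`.
#'
#' @param path YAML file.
#' @return A `"SyntheticSpec"`.
#' @export
readSynthSpecYaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  wp <- defaultWaveParams()
  for (w in names(y$waves %||% list())) {
    row <- match(toupper(w), wp$wave)
    if (is.na(row)) stop("unknown wave '", w, "' in spec")
    for (fld in names(y$waves[[w]]))
      wp[row, fld] <- y$waves[[w]][[fld]]
  }
  ns <- do.call(noiseSpec, y$noise %||% list())
  synthSpec(fs = y$fs %||% 1000, duration = y$duration %||% 10,
            heartRate = y$heartRate %||% 120,
            rrJitterSd = y$rrJitterSd %||% 0.01,
            waveParams = wp, noise = ns,
            anomaly = y$anomaly %||% list(type = "none"),
            seed = y$seed %||% 1L)
}
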