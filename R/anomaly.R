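# Rule-based per-interval anomaly diagnosis and run-length summarization.

#' Diagnostic criteria for zebrafish ECG anomalies
#'
#' Thresholds for the six rule-based diagnoses, chosen for zebrafish:
#' sinus bradycardia below 90 BPM, sinus tachycardia above 150 BPM, sinus
#' arrhythmia when the shortest and longest R-R of the last 10 heartbeats
#' differ by more than 0.16 s, sinus arrest when a P-P interval exceeds
#' twice the reference R-R. ST elevation/depression thresholds have no
#' established zebrafish values; the 0.1 mV defaults are explicitly
#' configurable placeholders.
#'
#' @param bradyBpm bradycardia threshold (BPM, default 90).
#' @param tachyBpm tachycardia threshold (BPM, default 150).
#' @param arrhythmiaSpread R-R spread threshold (s, default 0.16).
#' @param arrhythmiaWindow trailing window length in beats (default 10).
#' @param arrestFactor sinus-arrest multiple of the reference R-R
#'   (default 2).
#' @param stElevMv ST-elevation threshold on the mean ST-segment deviation
#'   (mV, default 0.1).
#' @param stDepMv ST-depression threshold (mV, default 0.1).
#' @return A list of class `"AnomalyCriteria"`.
#' @export
anomalyCriteria <- function(bradyBpm = 90, tachyBpm = 150,
                            arrhythmiaSpread = 0.16, arrhythmiaWindow = 10,
                            arrestFactor = 2, stElevMv = 0.1,
                            stDepMv = 0.1) {
  if (bradyBpm >= tachyBpm)
    stop("'bradyBpm' must be below 'tachyBpm'")
  if (arrestFactor <= 1) stop("'arrestFactor' must exceed 1")
  if (stElevMv <= 0 || stDepMv <= 0 || arrhythmiaSpread <= 0)
    stop("thresholds must be positive")
  cr <- list(bradyBpm = bradyBpm, tachyBpm = tachyBpm,
             arrhythmiaSpread = arrhythmiaSpread,
             arrhythmiaWindow = as.integer(arrhythmiaWindow),
             arrestFactor = arrestFactor,
             stElevMv = stElevMv, stDepMv = stDepMv)
  class(cr) <- "AnomalyCriteria"
  cr
}

ANOMALY_NAMES <- c(bradycardia = "Bradycardia",
                   tachycardia = "Tachycardia",
                   sinus_arrhythmia = "Arrhythmia",
                   sinus_arrest = "Sinus Arrest",
                   st_elevation = "ST Elevation",
                   st_depression = "ST Depression")

#' Diagnose anomalies for every R-R interval
#'
#' Applies the rule set per interval:
#' \itemize{
#'   \item bradycardia if the interval's instantaneous rate 60/RR is below
#'     `bradyBpm`; tachycardia if above `tachyBpm`;
#'   \item sinus arrhythmia if max-min R-R over the trailing window of up
#'     to `arrhythmiaWindow` beats (at least 2, fewer until 10 accumulate)
#'     exceeds `arrhythmiaSpread`;
#'   \item sinus arrest if the P-P span ending at this interval's P wave
#'     (measured from the most recent earlier interval with a detected P)
#'     exceeds `arrestFactor` times the reference R-R, the median R-R of
#'     the trailing window; intervals with no usable P-P are not evaluated;
#'   \item ST elevation/depression if the mean ST-segment deviation from
#'     the isoelectric line exceeds `+stElevMv` / falls below `-stDepMv`;
#'   \item normal rhythm if and only if no flag is raised.
#' }
#'
#' @param features data.frame from [computeIntervals()].
#' @param fiducials data.frame from [extractFiducials()].
#' @param stStats data.frame from [stSegmentStats()], or `NULL` to skip the
#'   ST rules.
#' @param criteria an [anomalyCriteria()].
#' @param fs sampling rate (Hz).
#' @return data.frame with one row per interval: `interval`, logical flags
#'   `bradycardia`, `tachycardia`, `sinus_arrhythmia`, `sinus_arrest`,
#'   `st_elevation`, `st_depression`, and `normal_rhythm`.
#' @export
diagnoseAnomalies <- function(features, fiducials, stStats = NULL,
                              criteria = anomalyCriteria(), fs = 1000) {
  if (nrow(features) == 0) stop("'features' must be nonempty")
  n <- nrow(features)
  rr <- features$RR
  bpm <- 60 / rr
  flags <- data.frame(interval = features$interval,
                      bradycardia = bpm < criteria$bradyBpm,
                      tachycardia = bpm > criteria$tachyBpm,
                      sinus_arrhythmia = FALSE, sinus_arrest = FALSE,
                      st_elevation = FALSE, st_depression = FALSE)

  w <- criteria$arrhythmiaWindow
  refRR <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- rr[max(1L, i - w + 1L):i]
    refRR[i] <- stats::median(win)
    if (length(win) >= 2 &&
        (max(win) - min(win)) > criteria$arrhythmiaSpread)
      flags$sinus_arrhythmia[i] <- TRUE
  }

  if (!is.null(fiducials) && "p" %in% names(fiducials)) {
    p <- fiducials$p
    lastP <- NA_integer_
    for (i in seq_len(n)) {
      if (!is.na(p[i]) && !is.na(lastP)) {
        pp <- (p[i] - lastP) / fs
        if (pp > criteria$arrestFactor * refRR[i])
          flags$sinus_arrest[i] <- TRUE
      }
      if (!is.na(p[i])) lastP <- p[i]
    }
  }

  if (!is.null(stStats)) {
    dev <- stStats$stDeviation[match(features$interval, stStats$interval)]
    flags$st_elevation <- !is.na(dev) & dev > criteria$stElevMv
    flags$st_depression <- !is.na(dev) & dev < -criteria$stDepMv
  }

  flagCols <- names(ANOMALY_NAMES)
  flags$normal_rhythm <- !Reduce(`|`, flags[flagCols])
  flags
}

#' Summarize a diagnosis into run-length rows
#'
#' Collapses consecutive intervals sharing an identical flag set into rows
#' of the form "first-last interval, anomaly names"; runs with no flags are
#' omitted, so an anomaly-free record yields an empty table.
#'
#' @param reports data.frame from [diagnoseAnomalies()], ordered by
#'   interval.
#' @return data.frame with columns `from`, `to` (1-based interval numbers,
#'   inclusive) and `anomalies` (comma-separated display names).
#' @examples
#' rep <- data.frame(interval = 1:4, bradycardia = c(TRUE, TRUE, TRUE, TRUE),
#'                   tachycardia = FALSE, sinus_arrhythmia = c(FALSE, FALSE,
#'                   TRUE, TRUE), sinus_arrest = FALSE, st_elevation = FALSE,
#'                   st_depression = FALSE)
#' rep$normal_rhythm <- FALSE
#' summarizeAnomalies(rep)  # "1-2 Bradycardia", "3-4 Bradycardia, Arrhythmia"
#' @export
summarizeAnomalies <- function(reports) {
  flagCols <- names(ANOMALY_NAMES)
  if (nrow(reports) == 0)
    return(data.frame(from = integer(), to = integer(),
                      anomalies = character()))
  key <- apply(reports[flagCols], 1, function(r) paste(as.integer(r),
                                                       collapse = ""))
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- lapply(seq_along(runs$values), function(j) {
    i <- starts[j]
    active <- unlist(reports[i, flagCols])
    if (!any(active)) return(NULL)
    data.frame(from = reports$interval[starts[j]],
               to = reports$interval[ends[j]],
               anomalies = paste(ANOMALY_NAMES[flagCols[active]],
                                 collapse = ", "))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(from = integer(), to = integer(),
                      anomalies = character()))
  do.call(rbind, rows)
}

#' Window-level flag display for streaming diagnosis
#'
#' Streaming (live-mode) frames display TRUE for an anomaly if any R-R
#' interval inside the current window was diagnosed with it, and normal
#' rhythm only if none was.
#'
#' @param reports data.frame from [diagnoseAnomalies()] restricted to the
#'   intervals of one window.
#' @return Named logical vector over the six anomaly flags plus
#'   `normal_rhythm`.
#' @export
windowFlags <- function(reports) {
  flagCols <- names(ANOMALY_NAMES)
  if (nrow(reports) == 0) {
    out <- stats::setNames(rep(FALSE, length(flagCols)), flagCols)
    return(c(out, normal_rhythm = TRUE))
  }
  out <- vapply(flagCols, function(cn) any(reports[[cn]]), logical(1))
  c(out, normal_rhythm = !any(out))
}
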