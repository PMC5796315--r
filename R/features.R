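# Interval, amplitude and ST-segment features, plus time-domain HRV.

#' Compute interval and amplitude features per R-R interval
#'
#' From the fiducials of interval i (between R1 and R2, with Q/S flanking
#' R1, T following R1, and P late in the interval preceding the next beat),
#' the intervals are, in seconds:
#' `RR = R2 - R1`, `QR = R1 - Q`, `RS = S - R1`, `ST = T - S`,
#' `RT = T - R1`, `TP = P - T`, `PR = R2 - P`, and
#' `PQ = Q(next interval) - P` (the conduction time from a P wave to the
#' QRS it precedes; NA for the final interval). The single amplitude
#' feature `RTAmp` is the signed difference between the R1 and T
#' amplitudes (mV).
#'
#' @param fiducials data.frame from [extractFiducials()].
#' @param fs sampling rate (Hz).
#' @return data.frame with one row per R-R interval: `interval`, the eight
#'   interval features, `RTAmp`, and `bpm` (= 60/RR). Missing fiducials
#'   propagate as NA features.
#' @export
computeIntervals <- function(fiducials, fs) {
  f <- fiducials
  sec <- function(d) d / fs
  nextQ <- c(f$q[-1], NA_integer_)
  out <- data.frame(
    interval = f$interval,
    RR = sec(f$r2 - f$r1),
    PQ = sec(nextQ - f$p),
    QR = sec(f$r1 - f$q),
    PR = sec(f$r2 - f$p),
    RS = sec(f$s - f$r1),
    ST = sec(f$t - f$s),
    RT = sec(f$t - f$r1),
    TP = sec(f$p - f$t),
    RTAmp = f$r1Amp - f$tAmp
  )
  out$bpm <- 60 / out$RR
  out
}

#' ST-segment statistics above and below the isoelectric line
#'
#' Takes the samples strictly between the S and T peaks of each interval,
#' splits them at the isoelectric value (samples exactly on the line count
#' as above), and reports per side the number of samples, their mean, and
#' their population (N-denominator) standard deviation. By default the
#' isoelectric line of an interval is the median of its T-to-P segment, the
#' conventional ECG baseline; a constant override may be supplied.
#'
#' @param record the [ECGRecord-class] the fiducials came from.
#' @param fiducials data.frame from [extractFiducials()].
#' @param isoelectric single numeric override (mV), or `NULL` (default) for
#'   the per-interval T-to-P median.
#' @return data.frame with one row per interval: `interval`, `isoelectric`,
#'   `nAbove`, `meanAbove`, `sdAbove`, `nBelow`, `meanBelow`, `sdBelow`,
#'   and `stDeviation` (mean of the whole ST segment minus the isoelectric
#'   value, the quantity used for ST elevation/depression diagnosis).
#'   Empty sides have count 0 and NA mean/SD.
#' @export
stSegmentStats <- function(record, fiducials, isoelectric = NULL) {
  stopifnot(is(record, "ECGRecord"))
  x <- ecgSamples(record)
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  n <- nrow(fiducials)
  out <- data.frame(interval = fiducials$interval, isoelectric = NA_real_,
                    nAbove = 0L, meanAbove = NA_real_, sdAbove = NA_real_,
                    nBelow = 0L, meanBelow = NA_real_, sdBelow = NA_real_,
                    stDeviation = NA_real_)
  for (i in seq_len(n)) {
    s <- fiducials$s[i]; t <- fiducials$t[i]; p <- fiducials$p[i]
    if (is.na(s) || is.na(t) || t - s < 2L) next
    iso <- if (!is.null(isoelectric)) isoelectric
           else if (!is.na(p) && p - t >= 2L)
             stats::median(x[(t + 1L):(p - 1L)])
           else 0
    seg <- x[(s + 1L):(t - 1L)]
    above <- seg[seg >= iso]
    below <- seg[seg < iso]
    out$isoelectric[i] <- iso
    out$nAbove[i] <- length(above)
    out$nBelow[i] <- length(below)
    if (length(above)) {
      out$meanAbove[i] <- mean(above); out$sdAbove[i] <- popSd(above)
    }
    if (length(below)) {
      out$meanBelow[i] <- mean(below); out$sdBelow[i] <- popSd(below)
    }
    out$stDeviation[i] <- mean(seg) - iso
  }
  out
}

#' Time-domain heart-rate and heart-rate-variability summary
#'
#' From the R-peak indices: per-interval instantaneous rate (60/RR), its
#' mean and standard deviation; mean and standard deviation of the R-R
#' interval lengths; RMSSD, the root mean square of successive R-R
#' differences; NN50, the number of adjacent R-R pairs differing by
#' strictly more than 50 ms; and pNN50 = 100 * NN50 / (#RR - 1). HRV
#' standard deviations use the sample (N-1) convention.
#'
#' @param rPeaks integer R-peak sample indices (>= 2; >= 3 for RMSSD).
#' @param fs sampling rate (Hz).
#' @return A list of class `"HRVSummary"` with elements `meanBpm`, `sdBpm`,
#'   `meanRR`, `sdRR`, `rmssd`, `nn50`, `pnn50`, `nIntervals`.
#' @examples
#' computeHRV(c(1, 501, 1001, 1501), fs = 1000)  # constant 0.5 s rhythm
#' @export
computeHRV <- function(rPeaks, fs) {
  if (length(rPeaks) < 2) stop("at least two R peaks are required")
  rr <- diff(rPeaks) / fs
  bpm <- 60 / rr
  drr <- diff(rr)
  if (length(rr) < 2 && length(drr) == 0)
    drr <- numeric(0)
  nn50 <- sum(abs(drr) > 0.050)
  res <- list(
    meanBpm = mean(bpm),
    sdBpm = if (length(bpm) > 1) stats::sd(bpm) else 0,
    meanRR = mean(rr),
    sdRR = if (length(rr) > 1) stats::sd(rr) else 0,
    rmssd = if (length(drr)) sqrt(mean(drr^2)) else NA_real_,
    nn50 = nn50,
    pnn50 = if (length(rr) > 1) 100 * nn50 / (length(rr) - 1) else NA_real_,
    nIntervals = length(rr)
  )
  class(res) <- "HRVSummary"
  res
}

#' @export
print.HRVSummary <- function(x, ...) {
  cat(sprintf(
    paste0("HRV over %d R-R intervals:\n",
           "  mean %.1f BPM (SD %.2f), mean R-R %.4f s (SD %.4f)\n",
           "  RMSSD %.4f s, NN50 %d, pNN50 %.1f%%\n"),
    x$nIntervals, x$meanBpm, x$sdBpm, x$meanRR, x$sdRR,
    x$rmssd, x$nn50, x$pnn50))
  invisible(x)
}
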