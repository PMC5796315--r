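# R-peak detection and windowed P/Q/S/T extraction per R-R interval.

#' Fiducial-extraction configuration
#'
#' Window geometry for the R-R windowing extractor: R peaks are local maxima
#' above a fraction of the maximum amplitude; Q and S are the minima within
#' 50 ms before/after each R; the T peak is the highest sample 15-55% of the
#' R-R interval after the first R; the P peak the highest sample 65-95% of
#' the interval after the first R.
#'
#' @param rThresholdFrac R threshold as a fraction of the maximum amplitude
#'   measured (default 0.5).
#' @param qsWindow Q/S search half-window in seconds (default 0.050).
#' @param tWindow T-wave search window as fractions of the R-R interval
#'   (default `c(0.15, 0.55)`).
#' @param pWindow P-wave search window as fractions of the R-R interval
#'   (default `c(0.65, 0.95)`).
#' @param refractory minimum separation between accepted R peaks in seconds
#'   (default 0.150); closer peaks collapse to the larger. Inert on clean
#'   recordings, protective under artifact spikes.
#' @return A list of class `"FiducialConfig"`.
#' @export
fiducialConfig <- function(rThresholdFrac = 0.5, qsWindow = 0.050,
                           tWindow = c(0.15, 0.55),
                           pWindow = c(0.65, 0.95), refractory = 0.150) {
  if (rThresholdFrac <= 0 || rThresholdFrac >= 1)
    stop("'rThresholdFrac' must lie in (0, 1)")
  for (w in list(tWindow, pWindow))
    if (length(w) != 2 || w[1] >= w[2] || w[2] > 1)
      stop("window fraction pairs must satisfy lo < hi <= 1")
  if (tWindow[2] > pWindow[1])
    stop("T and P windows must not overlap")
  cfg <- list(rThresholdFrac = rThresholdFrac, qsWindow = qsWindow,
              tWindow = tWindow, pWindow = pWindow, refractory = refractory)
  class(cfg) <- "FiducialConfig"
  cfg
}

#' Detect R peaks
#'
#' Finds local maxima whose amplitude reaches `rThresholdFrac` of the
#' maximum amplitude measured over the record, then collapses peaks closer
#' than the refractory period, keeping the larger. Intended for filtered
#' records, where the R wave is the only wave crossing half of the maximum.
#'
#' @param record an [ECGRecord-class] (typically the output of
#'   [filterPipeline()]).
#' @param cfg a [fiducialConfig()].
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based).
#' @export
detectRPeaks <- function(record, cfg = fiducialConfig()) {
  stopifnot(is(record, "ECGRecord"))
  x <- ecgSamples(record)
  if (length(x) < 3) stop("record too short for peak detection")
  thr <- cfg$rThresholdFrac * max(x)
  # local maxima: strictly greater than the previous sample, at least equal
  # to the next (ties break toward the earlier sample)
  core <- which(x[2:(length(x) - 1L)] > x[1:(length(x) - 2L)] &
                x[2:(length(x) - 1L)] >= x[3:length(x)]) + 1L
  peaks <- core[x[core] >= thr & x[core] > 0]
  if (length(peaks) == 0L) stop("no beats detected")
  refr <- round(cfg$refractory * samplingRate(record))
  kept <- peaks[1]
  for (p in peaks[-1]) {
    last <- kept[length(kept)]
    if (p - last < refr) {
      if (x[p] > x[last]) kept[length(kept)] <- p
    } else kept <- c(kept, p)
  }
  as.integer(kept)
}

#' Extract P, Q, S, T fiducials for every R-R interval
#'
#' For each consecutive R-peak pair (R1, R2): Q is the minimum within
#' `qsWindow` seconds before R1, S the minimum within `qsWindow` after R1,
#' T the maximum within `tWindow` fractions of the interval after R1, and P
#' the maximum within `pWindow` fractions after R1 (the P wave preceding
#' the next beat). Windows are inclusive of both endpoint samples, clamped
#' to the record (clamping is flagged), and argmax/argmin ties break toward
#' the earlier sample. A prominence score (peak amplitude minus the window
#' median) is attached to P and T so degenerate detections — e.g. a search
#' window containing no real wave after a dropped beat — can be screened.
#'
#' @param record an [ECGRecord-class].
#' @param rPeaks integer vector from [detectRPeaks()] (>= 2 peaks).
#' @param cfg a [fiducialConfig()].
#' @return data.frame with one row per R-R interval: `interval` (1-based),
#'   `r1`, `r2`, `p`, `q`, `s`, `t` (sample indices), `*Amp` amplitudes
#'   (mV), `pProminence`, `tProminence`, and `clamped` (logical).
#' @export
extractFiducials <- function(record, rPeaks, cfg = fiducialConfig()) {
  stopifnot(is(record, "ECGRecord"))
  if (length(rPeaks) < 2) stop("at least two R peaks are required")
  x <- ecgSamples(record)
  fs <- samplingRate(record)
  qs <- round(cfg$qsWindow * fs)
  n <- length(rPeaks) - 1L
  out <- data.frame(interval = seq_len(n), r1 = rPeaks[-length(rPeaks)],
                    r2 = rPeaks[-1], p = NA_integer_, q = NA_integer_,
                    s = NA_integer_, t = NA_integer_)
  out$clamped <- FALSE

  argAt <- function(lo, hi, fun) {
    lo2 <- max(1L, lo); hi2 <- min(length(x), hi)
    if (lo2 > hi2) return(list(idx = NA_integer_, clamped = TRUE,
                               prom = NA_real_))
    w <- x[lo2:hi2]
    k <- if (identical(fun, "max")) which.max(w) else which.min(w)
    list(idx = lo2 + k - 1L, clamped = (lo2 != lo || hi2 != hi),
         prom = w[k] - stats::median(w))
  }

  pProm <- tProm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r1 <- out$r1[i]; r2 <- out$r2[i]
    rr <- r2 - r1
    qres <- argAt(r1 - qs, r1 - 1L, "min")
    sres <- argAt(r1 + 1L, r1 + qs, "min")
    tres <- argAt(r1 + as.integer(round(cfg$tWindow[1] * rr)),
                  r1 + as.integer(round(cfg$tWindow[2] * rr)), "max")
    pres <- argAt(r1 + as.integer(round(cfg$pWindow[1] * rr)),
                  r1 + as.integer(round(cfg$pWindow[2] * rr)), "max")
    out$q[i] <- qres$idx; out$s[i] <- sres$idx
    out$t[i] <- tres$idx; out$p[i] <- pres$idx
    tProm[i] <- tres$prom; pProm[i] <- pres$prom
    out$clamped[i] <- qres$clamped || sres$clamped || tres$clamped ||
      pres$clamped
  }
  ampOf <- function(idx) ifelse(is.na(idx), NA_real_, x[idx])
  out$r1Amp <- ampOf(out$r1); out$r2Amp <- ampOf(out$r2)
  out$pAmp <- ampOf(out$p); out$qAmp <- ampOf(out$q)
  out$sAmp <- ampOf(out$s); out$tAmp <- ampOf(out$t)
  out$pProminence <- pProm
  out$tProminence <- tProm
  out
}
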