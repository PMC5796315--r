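# Shared builders for the test suite. All fixtures are generated in code.

# Noise-free, jitter-free record with ground truth.
quietRecord <- function(duration = 10, heartRate = 120, seed = 1,
                        anomaly = list(type = "none"), rrJitterSd = 0) {
  generateECG(synthSpec(duration = duration, heartRate = heartRate,
                        rrJitterSd = rrJitterSd, noise = quietNoise(),
                        anomaly = anomaly, seed = seed))
}

# Minimal fiducials table from R-R interval lengths (s) and optional P
# sample indices, for driving the rule engine directly.
fiducialsFromRR <- function(rr, fs = 1000, pOffsetFrac = 0.85,
                            pPresent = rep(TRUE, length(rr))) {
  r <- cumsum(c(1, round(rr * fs)))
  n <- length(rr)
  p <- ifelse(pPresent,
              r[seq_len(n)] + round(pOffsetFrac * rr * fs), NA_integer_)
  data.frame(interval = seq_len(n), r1 = r[seq_len(n)], r2 = r[-1],
             p = as.integer(p), q = r[seq_len(n)] - 20L,
             s = r[seq_len(n)] + 20L,
             t = r[seq_len(n)] + round(0.3 * rr * fs),
             r1Amp = 0.8, r2Amp = 0.8, pAmp = 0.1, qAmp = -0.08,
             sAmp = -0.1, tAmp = 0.15,
             pProminence = 0.1, tProminence = 0.15, clamped = FALSE)
}

featuresFromFiducials <- function(fid, fs = 1000) computeIntervals(fid, fs)

# Independent brute-force HRV oracle: plain-loop recomputation from first
# principles, kept free of package internals.
bruteHRV <- function(rr) {
  n <- length(rr)
  bpm <- numeric(n)
  for (i in seq_len(n)) bpm[i] <- 60 / rr[i]
  dsum <- 0
  nn50 <- 0
  for (i in seq_len(n - 1)) {
    d <- rr[i + 1] - rr[i]
    dsum <- dsum + d^2
    if (abs(d) > 0.050) nn50 <- nn50 + 1
  }
  list(meanBpm = sum(bpm) / n,
       sdBpm = sqrt(sum((bpm - sum(bpm) / n)^2) / (n - 1)),
       meanRR = sum(rr) / n,
       sdRR = sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)),
       rmssd = sqrt(dsum / (n - 1)),
       nn50 = nn50,
       pnn50 = 100 * nn50 / (n - 1))
}

flagColumns <- c("bradycardia", "tachycardia", "sinus_arrhythmia",
                 "sinus_arrest", "st_elevation", "st_depression")

activeFlags <- function(reports) {
  flagColumns[vapply(flagColumns, function(cn) any(reports[[cn]]),
                     logical(1))]
}
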