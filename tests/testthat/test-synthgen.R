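test_that("beat templates have the constructed geometry", {
  wp <- defaultWaveParams()
  fs <- 1000
  beat <- beatTemplate(wp, rr = 0.5, fs = fs)
  expect_length(beat, 500)
  # R is the global maximum, at its configured offset
  expect_equal(which.max(beat),
               round(wp$offset[wp$wave == "R"] * 0.5 * fs) + 1)
  # zero amplitudes give a zero beat
  wp0 <- wp; wp0$amp <- 0
  expect_equal(beatTemplate(wp0, 0.5, fs), rep(0, 500))
})

test_that("an isolated Gaussian wave integrates to amp * width * sqrt(2*pi)", {
  wp <- defaultWaveParams()
  wp$amp <- c(0, 0, 0.8, 0, 0)  # R alone at the 0.5 s reference interval
  beat <- beatTemplate(wp, rr = 0.5, fs = 10000)
  integral <- sum(beat) / 10000
  expect_equal(integral, 0.8 * wp$width[wp$wave == "R"] * sqrt(2 * pi),
               tolerance = 0.01)
})

test_that("generation yields the expected beat count and is seed-reproducible", {
  out <- quietRecord(duration = 10, heartRate = 120)
  nBeats <- nrow(truthBeats(out$truth))
  expect_true(abs(nBeats - 20) <= 1)
  out2 <- quietRecord(duration = 10, heartRate = 120)
  expect_identical(ecgSamples(out$record), ecgSamples(out2$record))
  expect_identical(truthBeats(out$truth), truthBeats(out2$truth))
  # different seed, different jittered record
  out3 <- generateECG(synthSpec(duration = 10, seed = 99))
  expect_false(identical(ecgSamples(out$record), ecgSamples(out3$record)))
  expect_error(generateECG(synthSpec(duration = 0.1, heartRate = 60)),
               "too short")
})

test_that("AVB injection drops QRS/T but keeps P waves", {
  out <- quietRecord(duration = 11, heartRate = 120,
                     anomaly = list(type = "avb", ratio = 2))
  b <- truthBeats(out$truth)
  expect_equal(sum(is.na(b$p)), 0)               # every beat keeps its P
  expect_equal(sum(b$dropped), floor(nrow(b) / 2))
  expect_true(all(is.na(b$r[b$dropped])))
  # the signal is flat at the dropped R locations
  det <- detectRPeaks(out$record)
  expect_equal(length(det), sum(!b$dropped))
})

test_that("SA injection creates a pause that fires the sinus-arrest rule", {
  out <- quietRecord(duration = 16, heartRate = 120,
                     anomaly = list(type = "sa", pauseBeats = 2))
  rp <- detectRPeaks(out$record)
  fid <- extractFiducials(out$record, rp)
  rep <- diagnoseAnomalies(computeIntervals(fid, 1000), fid,
                           stSegmentStats(out$record, fid), fs = 1000)
  expect_true(any(rep$sinus_arrest))
  # the pause spans roughly 3 base R-R intervals (two beats removed)
  rr <- diff(rp) / 1000
  expect_gt(max(rr), 2 * median(rr))
})

test_that("rate and rhythm injections satisfy their defining inequalities", {
  brady <- quietRecord(duration = 14, heartRate = 120,
                       anomaly = list(type = "bradycardia"))
  rrB <- diff(truthRPeaks(brady$truth)) / 1000
  expect_lt(mean(60 / rrB), 90)

  tachy <- quietRecord(duration = 14, heartRate = 120,
                       anomaly = list(type = "tachycardia"))
  rrT <- diff(truthRPeaks(tachy$truth)) / 1000
  expect_gt(mean(60 / rrT), 150)

  arr <- quietRecord(duration = 14, heartRate = 120,
                     anomaly = list(type = "sinus_arrhythmia"))
  rrA <- diff(truthRPeaks(arr$truth)) / 1000
  expect_gt(max(rrA) - min(rrA), 0.16)

  expect_error(quietRecord(anomaly = list(type = "bradycardia", bpm = 100)),
               "below 90")
  expect_error(quietRecord(anomaly = list(type = "nonsense")),
               "unknown anomaly")
})

test_that("STE injection elevates the ST segment by the configured offset", {
  stDev <- function(anomaly) {
    out <- quietRecord(duration = 10, heartRate = 120, anomaly = anomaly)
    rp <- detectRPeaks(out$record)
    fid <- extractFiducials(out$record, rp)
    stSegmentStats(out$record, fid)$stDeviation
  }
  elevated <- stDev(list(type = "ste", offset = 0.3))
  clean <- stDev(list(type = "none"))
  # same seed and geometry: the mean ST deviation rises by the offset
  # (the elevated plateau shifts the detected T peak by a sample)
  expect_lt(abs(mean(elevated - clean) - 0.3), 0.02)
})

test_that("noise-free records are recovered by the extractor (parameter recovery)", {
  for (seed in c(2, 13)) {
    out <- generateECG(synthSpec(duration = 10, heartRate = 120,
                                 rrJitterSd = 0.008, noise = quietNoise(),
                                 seed = seed))
    b <- truthBeats(out$truth)
    rp <- detectRPeaks(out$record)
    expect_equal(rp, truthRPeaks(out$truth), tolerance = 0)
    fid <- extractFiducials(out$record, rp)
    n <- nrow(fid)
    expect_lte(max(abs(fid$q - b$q[1:n])), 10)
    expect_lte(max(abs(fid$s - b$s[1:n])), 10)
    expect_lte(max(abs(fid$t - b$t[1:n])), 10)
    expect_lte(max(abs(fid$p - b$p[2:(n + 1)])), 10)
  }
})

test_that("the segment dataset is labeled, sized and reproducible", {
  ds <- makeSegmentDataset(nPerClass = 3, segmentLength = 3000, seed = 4)
  expect_equal(dim(ds$segments), c(9, 3000))
  expect_equal(as.vector(table(ds$labels)), c(3, 3, 3))
  ds2 <- makeSegmentDataset(nPerClass = 3, segmentLength = 3000, seed = 4)
  expect_identical(ds$segments, ds2$segments)
})
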