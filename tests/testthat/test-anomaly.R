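test_that("each constructed series triggers exactly its own rule", {
  fs <- 1000
  run <- function(fid) {
    feats <- computeIntervals(fid, fs)
    diagnoseAnomalies(feats, fid, stStats = NULL, fs = fs)
  }
  # 60 BPM regular -> bradycardia only
  expect_equal(activeFlags(run(fiducialsFromRR(rep(1.0, 12)))),
               "bradycardia")
  # 240 BPM regular -> tachycardia only
  expect_equal(activeFlags(run(fiducialsFromRR(rep(0.25, 12)))),
               "tachycardia")
  # spread 0.18 s over a 10-beat window -> sinus arrhythmia only
  rrSpread <- c(rep(0.49, 4), 0.40, rep(0.49, 4), 0.58, rep(0.49, 2))
  expect_equal(activeFlags(run(fiducialsFromRR(rrSpread))),
               "sinus_arrhythmia")
  # a dropped P makes the P-P span 2.2x the reference R-R -> sinus arrest
  pPresent <- rep(TRUE, 12); pPresent[6] <- FALSE
  fidArrest <- fiducialsFromRR(rep(0.5, 12), pPresent = pPresent)
  fidArrest$p[5] <- fidArrest$r1[5] + 375L   # P-P across the gap: 1.1 s
  fidArrest$p[7] <- fidArrest$r1[7] + 475L
  expect_equal(activeFlags(run(fidArrest)), "sinus_arrest")
  expect_true(run(fidArrest)$sinus_arrest[7])
  # 120 BPM regular -> nothing; normal rhythm throughout
  repNorm <- run(fiducialsFromRR(rep(0.5, 12)))
  expect_equal(activeFlags(repNorm), character(0))
  expect_true(all(repNorm$normal_rhythm))
})

test_that("normal rhythm is the negation of any flag and brady/tachy are exclusive", {
  fid <- fiducialsFromRR(c(rep(0.5, 5), rep(1.1, 5), rep(0.22, 5)))
  rep <- diagnoseAnomalies(computeIntervals(fid, 1000), fid, fs = 1000)
  expect_equal(rep$normal_rhythm,
               !Reduce(`|`, rep[flagColumns]))
  expect_false(any(rep$bradycardia & rep$tachycardia))
})

test_that("raising or lowering the bradycardia threshold is monotone", {
  fid <- fiducialsFromRR(runif(15, 0.4, 1.2))
  feats <- computeIntervals(fid, 1000)
  lo <- diagnoseAnomalies(feats, fid, criteria = anomalyCriteria(bradyBpm = 70),
                          fs = 1000)
  mid <- diagnoseAnomalies(feats, fid, fs = 1000)
  hi <- diagnoseAnomalies(feats, fid, criteria = anomalyCriteria(bradyBpm = 110),
                          fs = 1000)
  expect_true(all(!lo$bradycardia | mid$bradycardia))
  expect_true(all(!mid$bradycardia | hi$bradycardia))
  expect_error(anomalyCriteria(bradyBpm = 200), "below")
})

test_that("ST deviation beyond the thresholds sets elevation or depression", {
  fid <- fiducialsFromRR(rep(0.5, 4))
  feats <- computeIntervals(fid, 1000)
  st <- data.frame(interval = 1:4, stDeviation = c(0.05, 0.2, -0.2, -0.05))
  rep <- diagnoseAnomalies(feats, fid, st, fs = 1000)
  expect_equal(rep$st_elevation, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(rep$st_depression, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("summaries collapse runs of identical flag sets, skipping normal runs", {
  n <- 41
  rep <- data.frame(interval = 1:n, bradycardia = TRUE, tachycardia = FALSE,
                    sinus_arrhythmia = c(FALSE, FALSE, rep(TRUE, n - 2)),
                    sinus_arrest = FALSE, st_elevation = FALSE,
                    st_depression = FALSE)
  rep$normal_rhythm <- FALSE
  tab <- summarizeAnomalies(rep)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$from, c(1, 3))
  expect_equal(tab$to, c(2, 41))
  expect_equal(tab$anomalies,
               c("Bradycardia", "Bradycardia, Arrhythmia"))

  # no flags anywhere -> empty table
  clean <- rep
  clean$bradycardia <- FALSE
  clean$sinus_arrhythmia <- FALSE
  clean$normal_rhythm <- TRUE
  expect_equal(nrow(summarizeAnomalies(clean)), 0)

  # alternating flag sets -> one row per interval
  alt <- rep
  alt$sinus_arrhythmia <- rep(c(TRUE, FALSE), length.out = n)
  expect_equal(nrow(summarizeAnomalies(alt)), n)
})

test_that("diagnosis is deterministic and end-to-end sensitive and specific", {
  fid <- fiducialsFromRR(runif(20, 0.3, 1.0))
  feats <- computeIntervals(fid, 1000)
  expect_identical(diagnoseAnomalies(feats, fid, fs = 1000),
                   diagnoseAnomalies(feats, fid, fs = 1000))

  # injected anomalies are caught; clean records raise nothing
  endToEnd <- function(anomaly) {
    out <- quietRecord(duration = 14, heartRate = 120, anomaly = anomaly,
                       seed = 10)
    rp <- detectRPeaks(out$record)
    fid <- extractFiducials(out$record, rp)
    diagnoseAnomalies(computeIntervals(fid, 1000), fid,
                      stSegmentStats(out$record, fid), fs = 1000)
  }
  expect_true(any(endToEnd(list(type = "bradycardia"))$bradycardia))
  expect_true(any(endToEnd(list(type = "tachycardia"))$tachycardia))
  expect_true(any(endToEnd(list(type = "sinus_arrhythmia"))$sinus_arrhythmia))
  expect_true(any(endToEnd(list(type = "sa"))$sinus_arrest))
  expect_true(any(endToEnd(list(type = "ste"))$st_elevation))
  expect_true(all(endToEnd(list(type = "none"))$normal_rhythm))
})
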