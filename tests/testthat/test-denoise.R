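mkRecord <- function(x, fs = 1000) ECGRecord(x, fs = fs)

test_that("the lowpass passes DC and low frequencies, rejects the stopband", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  cfg <- filterConfig()
  # DC identity
  dc <- lowpassFilter(mkRecord(rep(0.7, 4000)), cfg)
  expect_lt(max(abs(ecgSamples(dc) - 0.7)), 1e-6)
  # 5 Hz passband: amplitude preserved within 1%
  lo <- lowpassFilter(mkRecord(sin(2 * pi * 5 * t)), cfg)
  mid <- 1000:3000
  expect_equal(max(abs(ecgSamples(lo)[mid])), 1, tolerance = 0.01)
  # 300 Hz stopband: RMS knocked down by >= 60 dB
  hi <- lowpassFilter(mkRecord(sin(2 * pi * 300 * t)), cfg)
  rms <- function(v) sqrt(mean(v^2))
  expect_lte(rms(ecgSamples(hi)[mid]), 1e-3 * rms(sin(2 * pi * 300 * t)))
  expect_error(lowpassFilter(mkRecord(rnorm(100), fs = 200), cfg),
               "Nyquist")
})

test_that("the lowpass is linear and length-preserving", {
  set.seed(5)
  x <- rnorm(2000); y <- rnorm(2000)
  cfg <- filterConfig()
  fx <- ecgSamples(lowpassFilter(mkRecord(x), cfg))
  fy <- ecgSamples(lowpassFilter(mkRecord(y), cfg))
  fxy <- ecgSamples(lowpassFilter(mkRecord(2 * x - 3 * y), cfg))
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
  expect_length(fx, 2000)
})

test_that("detrending removes slow drift and constants, sparing the beats", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  # sub-Hz sinusoid is almost entirely removed
  slow <- waveletDetrend(mkRecord(sin(2 * pi * 0.2 * t)))
  expect_lte(sqrt(mean(ecgSamples(slow)^2)), 0.05 * sqrt(0.5))
  # exact on constants, identity on zero
  expect_lt(max(abs(ecgSamples(waveletDetrend(mkRecord(rep(1.3, 4096)))))),
            1e-9)
  expect_equal(ecgSamples(waveletDetrend(mkRecord(rep(0, 2048)))),
               rep(0, 2048))
  # linear drift does not disturb detected R amplitudes (vs drift-free)
  out <- quietRecord(duration = 10)
  x <- ecgSamples(out$record)
  drift <- x + seq(0, 0.5, length.out = length(x))
  fNo <- waveletDetrend(mkRecord(x))
  fDr <- waveletDetrend(mkRecord(drift))
  rNo <- ecgSamples(fNo)[detectRPeaks(fNo)]
  rDr <- ecgSamples(fDr)[detectRPeaks(fDr)]
  expect_equal(length(rNo), length(rDr))
  expect_lt(max(abs(rDr - rNo) / abs(rNo)), 0.02)
})

test_that("shrinkage denoising suppresses white noise without breaking peaks", {
  out <- quietRecord(duration = 10)
  clean <- out$record
  # near-inert on a noiseless record: R amplitudes preserved within 5%
  den <- waveletDenoise(clean)
  tru <- truthRPeaks(out$truth)
  expect_lt(max(abs(ecgSamples(den)[tru] - ecgSamples(clean)[tru]) /
                  ecgSamples(clean)[tru]), 0.05)
  # does not increase energy
  expect_lte(sqrt(mean(ecgSamples(den)^2)),
             sqrt(mean(ecgSamples(clean)^2)) + 1e-9)
  # white noise (SD 0.5) on the quiet baseline is reduced >= 5x
  set.seed(31)
  noise <- rnorm(nSamples(clean), 0, 0.5)
  noisy <- mkRecord(ecgSamples(clean) + noise)
  filt <- filterPipeline(noisy)
  b <- truthBeats(out$truth)
  base <- unlist(lapply(seq_len(nrow(b) - 1), function(k)
    (b$t[k] + 120):(b$p[k + 1] - 60)))
  expect_lte(sd(ecgSamples(filt)[base]), sd(noise) / 5)
  expect_error(waveletDenoise(clean, filterConfig(denoiseRule = "sure")),
               "unknown denoise rule")
})

test_that("the canonical cascade order detects beats at least as well as a permuted order", {
  out <- generateECG(synthSpec(duration = 10, seed = 17))
  tru <- truthRPeaks(out$truth)
  f1For <- function(filtered) {
    rp <- tryCatch(detectRPeaks(filtered), error = function(e) integer())
    tp <- sum(vapply(tru, function(p) any(abs(rp - p) <= 10), logical(1)))
    prec <- if (length(rp)) tp / length(rp) else 0
    rec <- tp / length(tru)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  canonical <- f1For(filterPipeline(out$record))
  permuted <- f1For(lowpassFilter(waveletDetrend(
    waveletDenoise(out$record))))
  expect_gte(canonical, permuted)
  expect_equal(canonical, 1)
})

test_that("all cascade stages preserve length and are deterministic", {
  out <- generateECG(synthSpec(duration = 6, seed = 9))
  rec <- out$record
  f1 <- filterPipeline(rec)
  f2 <- filterPipeline(rec)
  expect_identical(ecgSamples(f1), ecgSamples(f2))
  expect_equal(nSamples(f1), nSamples(rec))
})
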