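# Synthetic zebrafish ECG generation with ground-truth annotations.
#
# Beats are modeled as five Gaussian bumps (P, Q, R, S, T; Q and S negative)
# placed at fixed fractions of the R-R interval, concatenated with jittered
# interval lengths and overlaid with configurable noise sources (baseline
# wander, mains hum, white noise, gill-motion bursts). Anomalies are
# injected structurally so that every downstream stage can be validated
# against exact ground truth.

#' Default zebrafish beat morphology
#'
#' Per-wave Gaussian parameters: amplitude (mV), width (s, the Gaussian
#' sigma), and the wave-center offset as a fraction of the R-R interval from
#' the start of the beat. The R wave dominates (so a 50%-of-max threshold
#' isolates R peaks), Q and S are narrow negative deflections flanking R
#' within 50 ms at physiological rates, the T wave follows within 15-55% of
#' the interval after R, and the P wave of the next beat falls 65-95% of the
#' interval after R. Zebrafish P/T amplitudes are not standardized; these
#' defaults are free parameters chosen to produce realistic-looking traces.
#'
#' @return data.frame with columns `wave`, `amp`, `width`, `offset`.
#' @export
defaultWaveParams <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.10, -0.08, 0.80, -0.10, 0.15),
    width  = c(0.015, 0.008, 0.010, 0.008, 0.035),
    offset = c(0.10, 0.16, 0.20, 0.24, 0.42),
    stringsAsFactors = FALSE
  )
}

#' Noise model for synthetic records
#'
#' @param baselineAmp baseline-wander amplitude (mV; default 0.2).
#' @param baselineFreq baseline-wander frequency (Hz; default 0.25,
#'   sub-Hz respiration/movement drift).
#' @param mainsAmp 60 Hz mains-hum amplitude (mV; default 0.05).
#' @param whiteSd white-noise standard deviation (mV; default 0.02).
#' @param gillAmp gill-motion burst amplitude (mV; default 0.1). Gill
#'   artifacts are modeled as randomly timed exponentially damped 2-4 Hz
#'   oscillation bursts.
#' @param gillRate mean gill-burst rate (bursts per second; default 0.5).
#' @return A list of class `"NoiseSpec"`.
#' @seealso [quietNoise()] for the all-zero noise model.
#' @export
noiseSpec <- function(baselineAmp = 0.2, baselineFreq = 0.25,
                      mainsAmp = 0.05, whiteSd = 0.02,
                      gillAmp = 0.1, gillRate = 0.5) {
  ns <- list(baselineAmp = baselineAmp, baselineFreq = baselineFreq,
             mainsAmp = mainsAmp, whiteSd = whiteSd,
             gillAmp = gillAmp, gillRate = gillRate)
  stopifnot(all(vapply(ns, function(v) is.finite(v) && v >= 0, logical(1))))
  class(ns) <- "NoiseSpec"
  ns
}

#' @rdname noiseSpec
#' @export
quietNoise <- function() {
  noiseSpec(baselineAmp = 0, mainsAmp = 0, whiteSd = 0,
            gillAmp = 0, gillRate = 0)
}

#' Specification of a synthetic zebrafish ECG record
#'
#' @param fs sampling rate (Hz; default 1000).
#' @param duration record length (s; default 10).
#' @param heartRate mean heart rate (BPM; default 120, a regular rhythm
#'   between the bradycardia and tachycardia thresholds). Presets: awake
#'   zebrafish run near 200 BPM, anesthetized near 100 BPM; pass those
#'   values explicitly to emulate either condition.
#' @param rrJitterSd standard deviation of per-beat R-R jitter (s;
#'   default 0.01).
#' @param waveParams per-wave morphology, see [defaultWaveParams()].
#' @param noise a [noiseSpec()]; use [quietNoise()] for noise-free records.
#' @param anomaly list with element `type`, one of `"none"`, `"avb"`,
#'   `"sa"`, `"ste"`, `"bradycardia"`, `"tachycardia"`,
#'   `"sinus_arrhythmia"`, plus type-specific parameters
#'   (see [injectAnomaly()]).
#' @param seed RNG seed; fixes the full output.
#' @return A list of class `"SyntheticSpec"`.
#' @export
synthSpec <- function(fs = 1000, duration = 10, heartRate = 120,
                      rrJitterSd = 0.01, waveParams = defaultWaveParams(),
                      noise = noiseSpec(), anomaly = list(type = "none"),
                      seed = 1L) {
  if (fs <= 0) stop("'fs' must be positive")
  if (duration <= 0) stop("'duration' must be positive")
  if (heartRate <= 0) stop("'heartRate' must be positive")
  if (any(waveParams$offset < 0 | waveParams$offset >= 1))
    stop("wave offsets must lie in [0, 1)")
  if (any(waveParams$width <= 0)) stop("wave widths must be positive")
  spec <- list(fs = fs, duration = duration, heartRate = heartRate,
               rrJitterSd = rrJitterSd, waveParams = waveParams,
               noise = noise, anomaly = anomaly, seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

#' Render one beat as a sum of Gaussian waves
#'
#' Wave widths are interpreted at a reference R-R of 0.5 s (120 BPM) and
#' scaled in proportion to the actual interval, so beat geometry — and the
#' non-overlap of adjacent waves — is rate-independent.
#'
#' @param waveParams per-wave parameters, see [defaultWaveParams()].
#' @param rr beat length (s).
#' @param fs sampling rate (Hz).
#' @return Numeric vector of `round(rr * fs)` amplitudes; the R wave is the
#'   global maximum when wave amplitudes follow the default ordering.
#' @export
beatTemplate <- function(waveParams, rr, fs) {
  n <- round(rr * fs)
  if (n < 2) stop("R-R interval too short at this sampling rate")
  centers <- waveParams$offset * rr
  sigma <- waveParams$width * rr / 0.5
  ord <- order(centers)
  sep <- diff(centers[ord])
  minSep <- sigma[ord][-nrow(waveParams)] + sigma[ord][-1]
  if (any(waveParams$amp != 0) && any(sep < minSep))
    stop("wave windows overlap: increase R-R or narrow the waves")
  t <- (seq_len(n) - 1L) / fs
  y <- numeric(n)
  for (i in seq_len(nrow(waveParams)))
    y <- y + waveParams$amp[i] *
      exp(-(t - centers[i])^2 / (2 * sigma[i]^2))
  y
}

# Index (1-based, within-beat) of a wave center for a beat of rr seconds.
waveIndex <- function(offset, rr, fs) as.integer(round(offset * rr * fs)) + 1L

#' Generate a synthetic zebrafish ECG record with ground truth
#'
#' Concatenates jittered Gaussian-morphology beats, injects the requested
#' anomaly (if any), and overlays additive noise. The returned ground truth
#' records the true sample index of every P/Q/R/S/T peak, dropped-QRS flags
#' for atrioventricular block, injected pauses, and any ST offset. The
#' output is fully reproducible from `spec$seed`.
#'
#' @param spec a [synthSpec()].
#' @return A list with elements `record` ([ECGRecord-class]) and `truth`
#'   ([ECGGroundTruth-class]).
#' @examples
#' out <- generateECG(synthSpec(duration = 5, heartRate = 120, seed = 42))
#' out$record
#' head(truthBeats(out$truth))
#' @export
generateECG <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    fs <- spec$fs
    nTotal <- round(spec$duration * fs)
    baseRR <- 60 / spec$heartRate
    if (spec$duration < baseRR)
      stop("duration too short for a single beat at ", spec$heartRate,
           " BPM")
    nBeats <- ceiling(spec$duration / baseRR) + 2L
    rr <- baseRR + stats::rnorm(nBeats, 0, spec$rrJitterSd)
    rr <- pmax(rr, 0.55 * baseRR)

    segs <- lapply(rr, function(r) beatTemplate(spec$waveParams, r, fs))
    lens <- vapply(segs, length, integer(1))
    starts <- cumsum(c(0L, lens[-length(lens)])) + 1L
    x <- unlist(segs, use.names = FALSE)

    wp <- spec$waveParams
    idxOf <- function(w, k)
      starts[k] + waveIndex(wp$offset[wp$wave == w], rr[k], fs) - 1L
    ks <- seq_len(nBeats)
    beats <- data.frame(
      beat = ks,
      p = vapply(ks, function(k) idxOf("P", k), integer(1)),
      q = vapply(ks, function(k) idxOf("Q", k), integer(1)),
      r = vapply(ks, function(k) idxOf("R", k), integer(1)),
      s = vapply(ks, function(k) idxOf("S", k), integer(1)),
      t = vapply(ks, function(k) idxOf("T", k), integer(1)),
      dropped = FALSE,
      start = starts,
      end = starts + lens - 1L
    )

    # trim to the requested duration at a beat boundary, so the signal
    # contains no partial beat absent from the ground truth
    keep <- beats$end <= nTotal
    beats <- beats[keep, , drop = FALSE]
    beats$beat <- seq_len(nrow(beats))
    if (nrow(beats) < 1L) stop("duration too short for one beat")
    x <- x[seq_len(beats$end[nrow(beats)])]

    record <- ECGRecord(x, fs = fs, channelId = "synth",
                        meta = list(generator = "zfecg-synthetic",
                                    heartRate = spec$heartRate,
                                    seed = spec$seed))
    truth <- new("ECGGroundTruth", beats = beats,
                 pauses = data.frame(start = integer(), end = integer()),
                 stOffset = 0)

    type <- spec$anomaly$type %||% "none"
    if (!identical(type, "none")) {
      inj <- injectAnomaly(record, truth, type, spec$anomaly)
      record <- inj$record
      truth <- inj$truth
    }

    record <- replaceSamples(record, ecgSamples(record) +
                               renderNoise(length(ecgSamples(record)),
                                           fs, spec$noise))
    list(record = record, truth = truth)
  })
}

# Additive noise: baseline wander + mains hum + white noise + gill bursts.
# Uses the current RNG stream (generateECG seeds it).
renderNoise <- function(n, fs, ns) {
  t <- (seq_len(n) - 1L) / fs
  y <- numeric(n)
  if (ns$baselineAmp > 0)
    y <- y + ns$baselineAmp *
      sin(2 * pi * ns$baselineFreq * t + stats::runif(1, 0, 2 * pi))
  if (ns$mainsAmp > 0)
    y <- y + ns$mainsAmp * sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
  if (ns$whiteSd > 0)
    y <- y + stats::rnorm(n, 0, ns$whiteSd)
  if (ns$gillAmp > 0 && ns$gillRate > 0) {
    nBursts <- stats::rpois(1, ns$gillRate * n / fs)
    for (b in seq_len(nBursts)) {
      t0 <- stats::runif(1, 0, n / fs)
      f <- stats::runif(1, 2, 4)     # gill-motion band
      tau <- 0.3                      # burst decay (s)
      m <- t >= t0
      y[m] <- y[m] + ns$gillAmp * exp(-(t[m] - t0) / tau) *
        sin(2 * pi * f * (t[m] - t0))
    }
  }
  y
}

#' Inject an anomaly pattern into a clean synthetic record
#'
#' Structural injection with exact bookkeeping in the ground truth:
#' \describe{
#'   \item{`avb`}{atrioventricular block: the QRS/T of every `ratio`-th
#'     beat (default 2) is erased, leaving its P wave; dropped beats are
#'     flagged and their Q/R/S/T indices set to NA.}
#'   \item{`sa`}{sinus arrest: `pauseBeats` consecutive beats (default 2,
#'     starting at `at`, default mid-record) are flattened to baseline,
#'     creating a pause whose P-P span exceeds twice the mean R-R.}
#'   \item{`ste`}{ST elevation: a constant `offset` (mV, default 0.3) is
#'     added to the samples between each beat's S and T peaks.}
#'   \item{`bradycardia`/`tachycardia`}{the whole record is time-rescaled
#'     so the mean rate equals `bpm` (defaults 75 / 180, beyond the 90 and
#'     150 BPM diagnostic thresholds).}
#'   \item{`sinus_arrhythmia`}{beats are piecewise time-warped so the R-R
#'     series alternates by `spread` seconds (default 0.2, above the 0.16 s
#'     diagnostic spread).}
#' }
#'
#' @param record a clean [ECGRecord-class] from [generateECG()].
#' @param truth its [ECGGroundTruth-class].
#' @param type anomaly name (see Details).
#' @param params list of type-specific parameters.
#' @return A list with updated `record` and `truth`.
#' @export
injectAnomaly <- function(record, truth, type, params = list()) {
  stopifnot(is(record, "ECGRecord"), is(truth, "ECGGroundTruth"))
  x <- ecgSamples(record)
  fs <- samplingRate(record)
  beats <- truth@beats
  type <- tolower(type)

  if (type == "avb") {
    ratio <- params$ratio %||% 2L
    if (ratio < 2) stop("'ratio' must be >= 2 for a conducted beat to remain")
    drop <- which(seq_len(nrow(beats)) %% ratio == 0L)
    for (k in drop) {
      # erase from just before Q to just after the T tail, sparing P
      from <- max(beats$start[k], beats$q[k] - round(0.02 * fs))
      to <- min(beats$end[k], beats$t[k] + round(0.12 * fs))
      x[from:to] <- 0
    }
    beats$dropped[drop] <- TRUE
    beats[drop, c("q", "r", "s", "t")] <- NA_integer_
  } else if (type == "sa") {
    pauseBeats <- params$pauseBeats %||% 2L
    at <- params$at %||% max(2L, floor(nrow(beats) / 2))
    to <- at + pauseBeats - 1L
    if (to >= nrow(beats))
      stop("pause of ", pauseBeats, " beats does not fit at beat ", at)
    from <- beats$start[at]
    upto <- beats$end[to]
    x[from:upto] <- 0
    pauses <- rbind(truth@pauses,
                    data.frame(start = from, end = upto))
    beats <- beats[-(at:to), , drop = FALSE]
    beats$beat <- seq_len(nrow(beats))
    return(list(record = replaceSamples(record, x, paste0("inject:", type)),
                truth = new("ECGGroundTruth", beats = beats,
                            pauses = pauses, stOffset = truth@stOffset)))
  } else if (type == "ste") {
    offset <- params$offset %||% 0.3
    for (k in seq_len(nrow(beats))) {
      if (beats$dropped[k]) next
      lo <- beats$s[k] + 1L
      hi <- beats$t[k] - 1L
      if (hi >= lo) x[lo:hi] <- x[lo:hi] + offset
    }
    return(list(record = replaceSamples(record, x, paste0("inject:", type)),
                truth = new("ECGGroundTruth", beats = beats,
                            pauses = truth@pauses, stOffset = offset)))
  } else if (type %in% c("bradycardia", "tachycardia", "sinus_arrhythmia")) {
    rrOld <- diff(beats$start) / fs
    meanRR <- mean(c(rrOld, (beats$end[nrow(beats)] -
                               beats$start[nrow(beats)] + 1L) / fs))
    if (type == "bradycardia") {
      bpm <- params$bpm %||% 75
      if (bpm >= 90) stop("bradycardia requires a target below 90 BPM")
      factors <- rep((60 / bpm) / meanRR, nrow(beats))
    } else if (type == "tachycardia") {
      bpm <- params$bpm %||% 180
      if (bpm <= 150) stop("tachycardia requires a target above 150 BPM")
      factors <- rep((60 / bpm) / meanRR, nrow(beats))
    } else {
      spread <- params$spread %||% 0.2
      if (spread <= 0.16)
        stop("sinus arrhythmia requires an R-R spread above 0.16 s")
      # R-R intervals span the tail of one beat and the head of the next:
      # with the R wave at relative position `rel` within the beat, beat
      # lengths alternating by +/-delta give an R-R spread of
      # 2*delta*(1-2*rel), so delta is scaled up accordingly.
      rel <- mean((beats$r - beats$start) /
                    (beats$end - beats$start + 1L), na.rm = TRUE)
      delta <- (spread / 2) / max(1 - 2 * rel, 0.1)
      if (meanRR - delta <= 0.05)
        stop("spread too large for the base R-R interval")
      factors <- (meanRR + ifelse(seq_len(nrow(beats)) %% 2 == 0,
                                  delta, -delta)) / meanRR
    }
    warped <- warpBeats(x, beats, factors)
    x <- warped$x
    beats <- warped$beats
  } else {
    stop("unknown anomaly type '", type, "'")
  }

  list(record = replaceSamples(record, x, paste0("inject:", type)),
       truth = new("ECGGroundTruth", beats = beats, pauses = truth@pauses,
                   stOffset = truth@stOffset))
}

# Piecewise-linear time warp: each beat segment is resampled to
# round(len * factor) samples; fiducial indices are remapped in proportion.
warpBeats <- function(x, beats, factors) {
  pieces <- vector("list", nrow(beats))
  newStart <- integer(nrow(beats))
  cursor <- 0L
  cols <- c("p", "q", "r", "s", "t")
  for (k in seq_len(nrow(beats))) {
    seg <- x[beats$start[k]:beats$end[k]]
    newLen <- max(2L, round(length(seg) * factors[k]))
    pieces[[k]] <- stats::approx(seq_along(seg), seg,
                                 xout = seq(1, length(seg),
                                            length.out = newLen))$y
    newStart[k] <- cursor + 1L
    for (cn in cols) {
      idx <- beats[[cn]][k]
      if (!is.na(idx)) {
        rel <- (idx - beats$start[k]) / (length(seg) - 1L)
        beats[[cn]][k] <- cursor + 1L + as.integer(round(rel * (newLen - 1L)))
      }
    }
    cursor <- cursor + newLen
    beats$end[k] <- cursor
  }
  beats$start <- newStart
  list(x = unlist(pieces, use.names = FALSE), beats = beats)
}

#' Build a labeled segment dataset for classifier validation
#'
#' Generates `nPerClass` synthetic ECG segments for each anomaly class
#' (default AVB, SA, STE — the gene-trap mutant phenotypes) under matched
#' conditions: a common 100 BPM anesthetized-like base rhythm so every
#' segment holds 4-5 beats in ~3000 samples at 1000 Hz, per-segment
#' amplitude jitter, small R-R jitter, and mild white noise. Segments are
#' beat-aligned by construction (each record starts at a beat onset), which
#' makes the classes separable in signal space.
#'
#' @param nPerClass segments per class (default 60).
#' @param classes character vector of anomaly classes; any subset of
#'   `c("AVB", "SA", "STE", "control")`.
#' @param segmentLength samples per segment (default 3000, roughly 4-5
#'   beats at 1000 Hz).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed fixing the whole dataset.
#' @return A list with `segments` (matrix, one row per segment) and
#'   `labels` (factor).
#' @export
makeSegmentDataset <- function(nPerClass = 60,
                               classes = c("AVB", "SA", "STE"),
                               segmentLength = 3000, fs = 1000, seed = 1L) {
  known <- c("AVB", "SA", "STE", "control")
  if (!all(classes %in% known))
    stop("classes must be among ", paste(known, collapse = ", "))
  anomalyFor <- list(
    AVB = list(type = "avb", ratio = 2L),
    SA = list(type = "sa", pauseBeats = 2L, at = 2L),
    STE = list(type = "ste", offset = 0.3),
    control = list(type = "none")
  )
  n <- nPerClass * length(classes)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  segs <- matrix(NA_real_, nrow = n, ncol = segmentLength)
  labels <- character(n)
  duration <- (segmentLength + 200) / fs
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      wp <- defaultWaveParams()
      ampJit <- withSeed(seeds[i], stats::runif(nrow(wp), 0.93, 1.07))
      wp$amp <- wp$amp * ampJit
      spec <- synthSpec(fs = fs, duration = duration, heartRate = 100,
                        rrJitterSd = 0.003, waveParams = wp,
                        noise = noiseSpec(baselineAmp = 0, mainsAmp = 0,
                                          whiteSd = 0.01, gillAmp = 0),
                        anomaly = anomalyFor[[cl]],
                        seed = seeds[i] %% (.Machine$integer.max - 1L))
      x <- ecgSamples(generateECG(spec)$record)
      if (length(x) < segmentLength)
        x <- c(x, numeric(segmentLength - length(x)))
      segs[i, ] <- x[seq_len(segmentLength)]
      labels[i] <- cl
    }
  }
  list(segments = segs, labels = factor(labels, levels = classes))
}
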