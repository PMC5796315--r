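---
title: "Methods: zebrafish ECG processing, diagnosis and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zebrafish ECG processing, diagnosis and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfecg)
```

# Scope and assumptions

`zfecg` analyzes single-channel, uniformly sampled zebrafish ECG traces.
The working assumptions throughout are: amplitudes in millivolts after any
acquisition gain is divided out; a sampling rate high enough (default
1000 Hz) that fiducial timing at millisecond precision is meaningful;
heart rates in the zebrafish range of roughly 60–240 BPM; and an R wave
that dominates every other wave in amplitude once baseline wander is
removed. The last assumption is what justifies the amplitude-threshold
R detector; recordings in which T waves rival R waves would need a lower
threshold or a slope-based detector, which this package does not provide.

# The denoising cascade

Three deterministic, length-preserving stages run in a fixed order.

**Lowpass.** A linear-phase FIR designed as a windowed sinc with a
Dolph-Chebyshev window (201 taps, 60 dB sidelobe attenuation, cutoff
150 Hz at fs = 1000 Hz), applied zero-phase with edge replication.
The cutoff is far above QRS energy (a ~10 ms Gaussian-like R deflection
concentrates below ~50 Hz) and far below the Nyquist frequency, so the
passband leaves the waves untouched while digitization and
electromyographic high-frequency noise are attenuated by three orders of
magnitude. Zero-phase application matters because fiducials are *timing*
measurements; a causal filter would shift every peak by the group delay.

**Wavelet detrend.** A multilevel periodized Daubechies-6 (db06)
decomposition in which the approximation band at the chosen level is
zeroed before reconstruction. The level is chosen as the smallest one
whose approximation band lies below 1 Hz (level 9 at 1000 Hz, band
0–0.98 Hz). Two competing constraints set this edge: baseline wander —
respiration, gill motion, electrode drift — lives below ~0.5 Hz, while
the slowest cardiac fundamental the package expects (~75 BPM after
bradycardia injection) sits at 1.25 Hz. An edge at 0.5 Hz leaves a 0.2 Hz
drift only ~93% removed because the db06 band transition is gradual; the
1 Hz edge removes it to below 3% RMS while staying clear of cardiac
energy. A constant offset is removed exactly (constants live entirely in
the approximation of an orthogonal wavelet transform).

**Wavelet denoise.** Soft thresholding of all detail coefficients at the
universal threshold σ√(2 log N). σ is the median absolute deviation
(scaled by 1/0.6745) of the finest detail level *inside the lowpass
passband* — level 3 at the default cutoff, band 62.5–125 Hz. Estimating σ
from level 1, the textbook choice, fails in a cascade: the preceding
lowpass empties the 250–500 Hz band, so the estimate collapses and the
threshold does nothing. The decomposition depth is the deepest level the
signal length supports, so the untouched approximation band falls inside
the already-detrended sub-Hz region and carries no surviving noise.

**Boundary handling.** The periodized transform treats the record as
circular; a record whose two ends differ (any drifting or truncated
trace) would ring at the wrap point. Both wavelet stages therefore
operate on the even extension `[x, rev(x)]` — continuous across the
boundary by construction — and keep the first half.

**Known behavior at very low SNR.** Universal soft thresholding
subtracts the threshold from every surviving coefficient. When broadband
noise approaches the R amplitude (e.g. 1 mV peak-to-peak noise against a
0.8 mV R wave), baseline noise is suppressed more than tenfold but R
amplitudes are visibly attenuated and deep-level shrinkage leaves a small
residual ripple. Detection still works on such records because the R
threshold is relative to the record's own maximum, but absolute
amplitudes after heavy denoising should not be over-interpreted.

# Fiducial extraction

R peaks are strict local maxima at or above 50% of the maximum amplitude
measured over the analysis window (the whole record in batch mode, the
trailing window in streaming mode), with peaks closer than a 150 ms
refractory period collapsed to the larger. The refractory period is inert
on clean data — at 240 BPM beats are still 250 ms apart — and exists to
reject double-counting under artifact spikes.

Within each interval between consecutive R peaks (R₁, R₂), windows
measured from R₁ locate the remaining peaks: Q = argmin on
[R₁ − 50 ms, R₁), S = argmin on (R₁, R₁ + 50 ms], T = argmax on
[R₁ + 0.15·RR, R₁ + 0.55·RR], P = argmax on [R₁ + 0.65·RR, R₁ + 0.95·RR].
The P found late in an interval is the P wave of the *next* beat. Window
endpoints are inclusive; argmax/argmin ties break to the earlier sample;
windows reaching past the record are clamped and the row flagged. The
last R peak opens no interval and beats before the first R are ignored —
the final partial beat has no defined windows, so it is simply omitted.
Because a window always returns *some* extremum, a prominence score (peak
minus window median) accompanies P and T so callers can screen
detections made in windows that contain no real wave (e.g. after a
dropped beat).

The windowing approach needs no derivative estimates or search tuning,
but it presumes the R detector is right: a missed R merges two intervals
and every windowed fiducial in them shifts accordingly.

# Features, HRV and diagnosis rules

Within interval (R₁, R₂): QR = R₁ − Q, RS = S − R₁, ST = T − S,
RT = T − R₁, TP = P − T, PR = R₂ − P, and PQ = Q(next interval) − P, the
conduction time from a P wave to the QRS it precedes. The PQ/PR
conventions deserve a note: since P is detected late in the interval
(zebrafish wave order), a "P-Q interval" can only reach forward into the
next interval; this choice is declared rather than standard. These
sub-intervals telescope: RS + ST + TP + PQ + QR(next) = RR exactly, a
property the tests assert. The single amplitude feature is the signed
R₁ − T amplitude difference.

ST-segment statistics take the samples strictly between S and T, split at
the isoelectric line (ties count as above), and report per-side count,
mean and population (N-denominator) standard deviation. The isoelectric
line defaults to the median of the same interval's T-to-P segment — the
conventional ECG baseline — with a constant override available.

The HRV block uses per-interval instantaneous rate 60/RR, sample (N−1)
standard deviations, RMSSD = √(mean(ΔRR²)), NN50 = #{|ΔRR| > 50 ms}
(strict inequality) and pNN50 = 100·NN50/(#RR − 1).

Diagnosis applies fixed zebrafish thresholds per R-R interval:
bradycardia below 90 BPM, tachycardia above 150 BPM (per-interval rate,
not a running mean), sinus arrhythmia when max − min R-R over the
trailing window of up to 10 beats exceeds 0.16 s (using however many
beats exist until 10 accumulate), and sinus arrest when the P-P span
ending at the current interval's P exceeds twice the reference R-R, taken
as the median R-R of the trailing 10-beat window. The P-P span is
measured from the most recent earlier interval with a detected P, so a
single undetectable P produces the long P-P a pause should; intervals
with no usable P-P are simply not evaluated for arrest. ST
elevation/depression fire when the mean ST-segment deviation from the
isoelectric line crosses ±0.1 mV — a configurable placeholder, since no
zebrafish reference values exist; quantitative claims should not lean on
these two flags. "Normal rhythm" is true exactly when no flag is raised.
Summary tables collapse maximal runs of identical flag sets into
"first–last → anomaly names" rows and omit normal runs.

Atrioventricular block is deliberately absent from the rule vocabulary:
it is handled by the classifier below, not by thresholds.

# Streaming mode

Live monitoring is emulated by replaying the record in trailing windows
(default 10 s, hop 1 s). Each frame filters and diagnoses its window
independently and displays the OR of the per-interval flags, with frames
before a full window marked as warming up. Re-filtering per window means
wavelet edge effects can differ slightly from the batch run near window
boundaries; on quiet records batch and streaming agree exactly (asserted
in the tests), on noisy ones an occasional boundary-interval flag can
differ.

# Synthetic records and what they do (not) show

Each beat is five Gaussian bumps — P, Q, R, S, T with amplitudes
(0.10, −0.08, 0.80, −0.10, 0.15) mV, centers at (0.10, 0.16, 0.20, 0.24,
0.42) of the R-R interval from beat onset, and widths (15, 8, 10, 8,
35) ms referenced to a 0.5 s interval and scaled with it. Zebrafish P/T
amplitudes are not standardized anywhere; these are free parameters
chosen so the R dominates (validating the 50% threshold), Q/S fall inside
the ±50 ms search windows at all supported rates, and T and the next P
fall inside their fractional windows. Beats are concatenated with
Gaussian R-R jitter (SD 10 ms) and overlaid with additive noise:
sub-Hz sinusoidal baseline wander (0.2 mV at 0.25 Hz), 60 Hz hum
(0.05 mV), white noise (SD 0.02 mV), and gill-motion artifacts modeled as
Poisson-timed exponentially damped 2–4 Hz bursts (0.1 mV, 0.5/s) — gill
artifacts dominate real awake recordings but have no published waveform
model, so a damped oscillation in the gill-beat band stands in. The
default rate is 120 BPM, a regular rhythm between the two rate
thresholds; awake fish run near 200 BPM and anesthetized fish near
100 BPM, and both are available by passing those rates explicitly.

Anomaly injection is structural and bookkept exactly: AV block erases the
QRS/T of every k-th beat (default 2:1) leaving its P; sinus arrest
flattens whole beats to baseline, producing a pause with P-P ≈ 3× the
mean R-R by default; ST elevation adds a constant (default +0.3 mV)
between each beat's S and T; bradycardia/tachycardia time-rescale the
record to 75/180 BPM; sinus arrhythmia piecewise-warps beats so the R-R
series alternates with a 0.2 s spread — the warp compensates for the R
sitting at 20% of the beat, without which the R-to-R spread would be only
60% of the beat-length spread. All generation is driven by one seeded
RNG stream per call, with the caller's RNG state restored afterwards.

Passing recovery and classification tests on these records demonstrates
*internal correctness* — the extractor finds the peaks the generator
placed, the rules fire on the patterns their definitions describe, the
classifier separates classes that differ the way the mutant phenotypes
differ. It does not demonstrate performance on real recordings, whose
artifacts are not Gaussian bumps plus stationary noise, whose P/T waves
are often barely visible in awake fish, and whose class differences are
subtler than the injected ones.

# Classification pipeline

Segments of roughly 4–5 beats (~3000 samples at 1000 Hz) are truncated to
the largest leading perfect square — 2916 samples, side 54 — and either
encoded as z-layout images (row-major fill, first sample top-left,
amplitudes mapped affinely from the segment's [min, max] onto [0, 255],
constant segments to mid-grey 128) or fed to K-means directly as min-max
normalized 1-D vectors. The published pipeline does not say whether
K-means saw signals or images; the package clusters the normalized
signals — the min-max normalization makes either representation
equivalent up to reshaping — and reserves images for the optional CNN
adapter and for inspection.

K-means is Lloyd's iteration: centroids start at k distinct points drawn
at random under an explicit seed, points move to their nearest centroid,
centroids move to their member means, until the assignment is a fixed
point (with a 300-iteration cap and 1e-6 centroid-movement tolerance). An
emptied cluster is re-seeded from the point farthest from its centroid.
Random initialization on well-separated clusters can still merge two of
them (a known local optimum), so the fit runs `nstart` independent
restarts (25 by default, 40 inside cross-validation) and keeps the lowest
within-cluster sum of squares; with three tight, well-separated classes
the chance that no restart seeds all three is then negligible. Clusters
are mapped to labels by training-set majority, ties breaking to the first
class level.

Evaluation builds the confusion matrix (rows actual, columns predicted),
derives one-vs-rest TP/FP/FN/TN per class, and macro-averages: accuracy
is the equal-weight mean of per-class (TP+TN)/total, precision and recall
the means of the per-class ratios, and F1 = 2PR/(P+R) applied to the
macro precision and recall — the same arithmetic that connects the
published per-class and average rows. Cross-validation is stratified
(round-robin within class after a seeded shuffle) into 10 folds; each
fold is predicted by nearest centroid from a fit on the other nine, and
fold metrics are averaged. A class absent from a test fold would have
undefined recall and is excluded from that fold's macro average with a
note.

The CNN transfer-learning adapter is an interface only: training one
requires a pretrained image backbone, which the package does not ship.
`registerCnnBackbone()` lets an environment that has one plug it in;
without it the adapter reports itself disabled and the K-means path is
unaffected.

# Problem sizes and numerical choices

The test suite and the acceptance script use 10–15 s records (~20–30
beats) for recovery and rule checks, 1000 random R-R series against a
brute-force HRV oracle at 1e-12 agreement, and a classification dataset
of 60 segments per class × 3 classes (the same order as the published
488-sample experiments), which cross-validates in well under a minute on
one core. Reconstruction accuracy of the wavelet transform is at machine
precision (asserted at 1e-12); filter linearity at 1e-9; fiducial
recovery tolerances are ±2 ms for R and ±10 ms for P/Q/S/T — the
overlapping R-wave tail shifts the Q/S minima by a few milliseconds at
default morphology, which is within the recovery band by design.

# Limitations

Single-channel only; no wave onset/offset delineation (intervals are
peak-to-peak); no frequency-domain HRV; ST thresholds are placeholders;
the rule engine assumes reliable P detection for sinus arrest; the
classifier's perfect synthetic scores reflect the generator's
separability, not expected field performance; and the streaming mode
replays files rather than interfacing acquisition hardware.
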