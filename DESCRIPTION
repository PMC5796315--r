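Package: zfecg
Title: Zebrafish Electrocardiogram Processing, Anomaly Diagnosis and
    Pattern Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing zebrafish electrocardiogram (ECG)
    recordings: a three-stage denoising cascade (Dolph-Chebyshev lowpass,
    Daubechies-6 wavelet detrending and wavelet shrinkage denoising),
    R-peak detection with windowed P/Q/S/T fiducial extraction per R-R
    interval, interval and ST-segment features, time-domain heart-rate
    variability statistics (RMSSD, NN50, pNN50), rule-based diagnosis of
    sinus bradycardia, tachycardia, arrhythmia, arrest and ST deviation,
    z-layout greyscale image encoding of beat segments, and K-means
    classification of anomaly patterns with stratified cross-validated
    macro-averaged evaluation. A seeded synthetic zebrafish-ECG generator
    with ground-truth annotations supports validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'wavelet.R'
    'io.R'
    'synthgen.R'
    'denoise.R'
    'fiducials.R'
    'features.R'
    'anomaly.R'
    'classify.R'
    'cli.R'
    'zfecg-package.R'
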