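Package: hivewhoop
Title: Detection and Characterisation of Honeybee Whooping Signals in
    Long-Duration Hive Vibration Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding brief honeybee "whooping" (stop-signal)
    vibrational pulses in continuous two-channel accelerometer recordings of
    hive frames. Implements a two-pass detector (spectrogram template matching
    by the ratio of the cross-correlation product to the Euclidean distance,
    followed by discriminant-function analysis on PCA scores of spectrogram
    patches), per-pulse physical characterisation (fundamental frequency,
    duration, amplitude, harmonic profile), two-channel duplication analysis
    with the 10 ms coincidence rule and the derived sensor-coverage
    arithmetic, and long-term occurrence statistics (hourly heatmaps, daily
    profiles, daily mean spectra, modal amplitudes). A deterministic synthetic
    hive-vibration generator produces two-channel sessions with ground-truth
    event logs so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'characterize.R'
    'colocation.R'
    'config.R'
    'spectral.R'
    'detection.R'
    'discrimination.R'
    'eventlog.R'
    'hivesynth.R'
    'hivewhoop-package.R'
    'persist.R'
    'trends.R'
    'wav.R'
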