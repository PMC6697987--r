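Package: tremorprofile
Title: Personalised Tremor Profiling from Multichannel Movement Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies upper-limb tremor from multichannel movement
    recordings (joint angles and hand acceleration) and tracks clinically
    relevant changes in an individual's symptoms. Tremor amplitudes are
    extracted per movement parameter via Welch power spectral density and a
    calibrated average-tremor-amplitude (ATA) estimator with heuristic
    rejection of unreliable spectra. Per-subject characteristic vectors
    summarise each individual's typical blend of tremor across joints, and
    change between visits is decomposed into scale (parallel to the
    characteristic vector), scale2 (squared-profile weighting), profile
    (perpendicular), and mean-difference metrics, each normalised by the
    subject's own same-day variability. An evaluation harness correlates the
    metrics against clinical rating-scale changes with Benjamini-Hochberg
    false-discovery-rate control, and a synthetic cohort/signal generator
    provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    optparse
Config/testthat/edition: 3
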