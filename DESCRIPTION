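Package: beelfp
Title: Honeybee Optic-Lobe Local Field Potential Analysis During Flight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel local field potential (LFP)
    recordings from the honeybee optic lobe during electrically evoked flight.
    Provides DC removal by forward/inverse discrete Fourier transform,
    baseline-wander correction by empirical mode decomposition with
    low-frequency intrinsic-mode-function removal, Burg autoregressive power
    spectral density estimation, spectral feature extraction for
    flapping/calm state discrimination (20-30 Hz peak, 0-15 Hz band power,
    spectral fluctuation), transition-frequency location between state-average
    spectra, and behavioral statistics for stimulation trials (success-rate
    grids, grid refinement, flapping frequency/duration summaries and
    correlation). A seeded synthetic-data module generates LFP traces and
    stimulation trial tables with the statistical structure the analysis
    assumes, so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
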