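Package: eegssa
Title: Adaptive Singular Spectrum Analysis for Single-Channel EEG
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Artifact removal and brain-rhythm extraction from single-channel
    electroencephalography (EEG) by singular spectrum analysis (SSA) with an
    adaptive grouping rule: the first one or two reconstructed components are
    removed as artifacts depending on the signal amplitude, remaining
    components are paired by eigenvalue similarity into periodic components,
    and groups are assigned to the canonical rhythm bands (delta, theta,
    alpha, beta, gamma) by their Fourier peak frequency. Includes a Markov
    Process Amplitude (MPA) EEG simulator with configurable ocular-artifact
    (EOG) pulse trains, sinusoidal baseline drift and measurement noise, band
    power features, and eyes-open/eyes-closed state classification, plus CSV
    input/output and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
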