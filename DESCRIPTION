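Package: oddbeat
Title: Simulation and Single-Case Analysis of Beat-Omission Oddball ERP Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditory beat-omission oddball experiments of the kind
    used to study beat deafness. Builds the drum-pattern stimulus schedules
    (passive "ignore" streams, deviant-only control blocks, and active
    detection trials), simulates multi-channel EEG recordings with embedded
    event-related components (MMN, P3a, P3b), 1/f background noise and blink
    artifacts, plus behavioral keypress responses; runs the standard ERP
    preprocessing chain (bandpass filtering, epoching, peak-to-peak artifact
    rejection, baseline correction, selective averaging); quantifies
    components on region-of-interest difference waves (peak latencies, 40-ms
    mean amplitudes, noise-based reliability verdicts); and provides the
    inferential layer for single-case neuropsychology: Crawford modified
    t-tests against a small control sample, leave-one-out control analyses,
    two-level repeated-measures ANOVA, and the Zhang-Mueller nonparametric
    signal-detection measures of sensitivity (A) and bias (b).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    zoo,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
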