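Package: lfpkit
Title: Laminar LFP and EEG Analysis of Hippocampal Oscillations, Evoked
    Responses and Stereology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hippocampal electrophysiology from laminar
    silicon-probe recordings and chronic epidural EEG: zero-phase FIR
    filtering, Savitzky-Golay smoothing and Hilbert envelopes; averaged
    Hamming-tapered power spectra in decibels with 1/f normalization and
    band-power areas; multitaper time-frequency maps; current-source-density
    and rule-based identification of hippocampal strata; threshold-based
    detection and characterization of sharp-wave ripples and sleep spindles;
    evoked fEPSP, afferent-volley and population-spike measures with
    input/output curves and paired-pulse ratios; Cavalieri stereology and
    heterotopia geometry; group statistics; and a fully seeded synthetic-data
    generator with ground truth for detector benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
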