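Package: capblink
Title: Capacitive Blink Detection and Fatigue Scoring from
    Resonance-Frequency Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eyewear-mounted capacitive blink sensing. An
    electrode near the eye forms an RLC tank whose resonance frequency
    dips when the eyelid (a high-permittivity dielectric) passes in front
    of the plate. The package provides the closed-form capacitance and
    resonance forward model, a seeded physics-based generator of labelled
    synthetic recordings, Gaussian-weight interpolation of jittered
    samples onto a uniform grid, a high-order Butterworth band-pass
    realized as second-order sections, derivative-threshold blink
    detection with confidence fusion, per-window blink-feature
    extraction, fatigue self-assessment (FSAS) scoring, and a small
    feed-forward backpropagation network mapping blink features to a
    fatigue scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    nnet,
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
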