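Package: fibromark
Title: Equivalent-Circuit Impedance Modelling and Voltage-Waveform Markers
    of Fibrotic Encapsulation on Neural Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking fibrotic tissue encapsulation around
    stimulating neural electrodes (cochlear-implant arrays in particular)
    from their electrical signatures. Implements a constant-phase-element
    (CPE) equivalent circuit of a fibrosing electrode, quality screening
    and complex-modulus-weighted nonlinear least-squares fitting of
    electrochemical impedance spectroscopy (EIS) sweeps over a time
    course, closed-form simulation of voltage responses to biphasic
    charge-balanced current pulses, extraction of clinically measurable
    markers (contact "impedance" and the second phase peak ratio, SPPR),
    reverse fitting of bulk circuit elements from voltage waveforms by
    bounded grid-multistart optimisation, and a seeded synthetic cohort
    generator with fibrosis-like parameter trajectories for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
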