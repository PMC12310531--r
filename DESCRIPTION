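Package: mitoclock
Title: Compartment-Resolved CDK Activation Timing from Single-Cell Sensor Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing when mitotic cyclin-dependent kinase (CDK)
    activity switches on in the nucleus versus the cytoplasm of single cells.
    Includes a mechanistic synthetic-data generator (a two-compartment
    bistable cyclin-CDK oscillator with translocation biosensor kinetics, a
    timelapse image renderer and a phosphosite timecourse generator),
    compartment mean-intensity quantification with the top-fraction and
    nuclear-mask estimators, piecewise-linear change-point detection of
    activation times and nuclear-to-cytoplasmic delays, phase-orbit and
    hysteresis metrics, exponential decay and dose-response kinetics fits,
    and compartment-wise phosphosite timing statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
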