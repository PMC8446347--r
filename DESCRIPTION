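Package: cpgrate
Title: Firing-Rate Models of Spinal Central Pattern Generator Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate network models of a spinal central pattern generator
    (CPG) module in two architectures: recurrent excitation curbed by intrinsic
    adaptation, and recurrent excitation balanced by recurrent inhibition.
    Provides forward-Euler integration of the rate dynamics with a saturating
    tanh nonlinearity, truncated-Gaussian random connectivity, pulsed external
    drive protocols, Galton-Watson branching-process simulation with
    avalanche-size power-law fitting for criticality analysis, peak firing-rate
    distribution statistics (skewness, lognormal maximum likelihood fits,
    histogram modes), and a synthetic calcium-imaging generator emulating
    per-animal populations of dF/F traces for cohort-level skewness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    fitdistrplus
Config/testthat/edition: 3
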