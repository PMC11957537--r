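Package: LineageHomeo
Title: Single-Cell Lineage Statistics and Cell-Size Homeostasis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-lapse single-cell lineage data from
    bacterial microcolonies: per-object shape morphometrics (compactness and
    shape-branched volume estimation), sister-cell asymmetry statistics for
    elongation rate, division time and septum placement, binomial
    survival-probability estimation with Wald intervals, adder-model added
    volume and elongation/septation homeostasis diagnostics, Young-Laplace
    thin-shell predictions for the rod-to-sphere transition, and bulk-culture
    fitness and growth-curve formulas. Includes an agent-based lineage
    simulator with calibrated sister asymmetry and volume-dependent survival
    so every analysis stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
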