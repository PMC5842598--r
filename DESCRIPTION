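Package: cbdens
Title: Cumulative Breast Density and Two-Stage Carcinogenesis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing cumulative mammographic breast density
    (CBD, "breast density years") from cross-sectional cohorts, calibrating
    magnetic-resonance percent breast water to a mammographic-density
    equivalent, fitting power-law (log-log) models of age-specific breast
    cancer incidence against age and CBD, and simulating the Moolgavkar
    two-stage clonal-expansion model of carcinogenesis with a
    reproductive-history-dependent susceptible-cell population. Includes a
    synthetic-data module that generates median-exact cohorts, calibration
    pairs, and incidence series so the whole pipeline can be exercised
    without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
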