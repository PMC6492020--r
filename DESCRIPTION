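Package: xylemct
Title: Quantification of Drought-Induced Xylem Embolism from Micro-CT
    Cross-Sections
Version: 0.1.0
Authors@R:
    person("Plant Hydraulics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify drought-induced xylem embolism in plant
    organs from micro-CT cross-section images: segmentation of air-filled
    conduits, anatomical statistics (vessel density, hydraulically
    weighted diameter, diameter class histograms, wall reinforcement),
    theoretical Hagen-Poiseuille conductance and percentage loss of
    conductivity from matched initial/final scan pairs, Weibull
    vulnerability-curve fitting with bootstrap confidence intervals for
    the P12/P50/P88 thresholds, and a synthetic cross-section generator
    that provides ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
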