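Package: triphase
Title: Tri-Phase Quantification of Leaf Growth Responses to Soil Water Deficit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies when graminoid leaf growth slows and arrests under
    increasing soil water deficit from high-frequency leaf-length, meristem
    temperature and soil matric potential time series. Hourly leaf elongation
    rates are corrected for temperature via a through-origin thermal growth
    rate, binned by quarter intervals of log10 soil water potential, and the
    slow phase is fitted by linear regression to estimate the breakpoints at
    which growth begins to slow (Sigma) and stops (sigma). Includes a
    synthetic-experiment simulator with known piecewise-linear ground truth
    for validating the fitting pipeline by parameter recovery, relative water
    content computation, and one-way ANOVA comparison of replicated
    experiments and genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
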