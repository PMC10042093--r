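Package: cvdrecal
Title: External Validation and Regional Recalibration of Cardiovascular
    Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for externally validating and regionally recalibrating
    non-laboratory 10-year cardiovascular disease risk models with
    sex-specific coronary and stroke submodels. Provides censoring-aware
    discrimination and calibration statistics (Harrell's C with confidence
    intervals, Kaplan-Meier decile calibration, predicted-to-observed
    ratios, the Nam-D'Agostino chi-square test), stratum-wise recalibration
    on the cumulative-hazard scale, random-effects pooling of regional
    concordance indices, and a synthetic multi-region cohort simulator so
    the full before/after-recalibration study design can be exercised and
    tested without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    metafor,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
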