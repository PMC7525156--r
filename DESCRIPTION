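Package: gtmr
Title: Two-Sample Mendelian Randomization of Glycemic Traits on Breast Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: harmonization of exposure and outcome panels to a common
    effect allele, the fixed-effect inverse-variance weighted (IVW)
    estimator, Cochran's Q heterogeneity test, MR-Egger regression for
    directional pleiotropy, cross-dataset pooling, and leave-one-out
    sensitivity analysis. Ships the per-variant association tables for
    fasting glucose and fasting insulin instruments against breast cancer
    (MAGIC exposures; BCAC OncoArray and ATLAS CGEMS/GEEA/GEEAB outcomes)
    as a packaged fixture, plus a synthetic two-sample summary-statistic
    generator for estimator calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
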