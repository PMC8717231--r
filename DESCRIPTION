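Package: exmort
Title: Excess Mortality Estimation from Monthly Death Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates excess all-cause mortality for a target year from
    multi-unit panels of monthly death counts and annual population
    exposures. Computes month-length-adjusted crude death rates, fits
    seasonal fixed-effects baselines with and without a linear secular
    trend as well as a Lee-Carter sensitivity baseline, derives annual and
    quarterly absolute and relative excess with residual-bootstrap
    confidence intervals, and relates excess to reported epidemic burden
    across units via correlation, regression, and local Moran's I spatial
    cluster statistics. Includes a synthetic panel generator with known
    ground truth for validation, a weekly-to-monthly death count
    disaggregator for STMF-style series, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
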