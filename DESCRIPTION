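Package: lakecor
Title: Interannual Lake Chlorophyll-Temperature Correlation Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lake-wide interannual associations between satellite
    surface chlorophyll-a and lake surface temperature from gapped gridded
    observations. Computes fields of Kendall rank correlations over
    pixel-by-season subdivisions, removes spatial and seasonal sampling bias
    with a boosted-regression-tree resampling estimator, explains cross-lake
    variation in the debiased correlations with a weighted boosted regression
    tree on lake attributes, and validates satellite retrievals against in
    situ samples with standardized major axis regression. Includes a
    Gaussian-copula synthetic-data generator with known ground truth so the
    whole pipeline can be exercised offline, and a small gradient-boosting
    engine (squared-error loss, observation weights, missing-value routing,
    cross-validated tree selection, relative influence, partial dependence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
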