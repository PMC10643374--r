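Package: foodenv
Title: Activity-Based and Location-Based Retail Food Environment Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the retail food activity index (RFAI), an
    activity-based census-tract food environment measure built from
    origin-destination visit flows to NAICS-classified food retailers, and
    the location-based modified retail food environment index (mRFEI).
    Computes tract-level mobility summaries (visit-weighted median travel
    distance, distance-band shares, half-mile buffer shares), and estimates
    covariate-adjusted associations between the indices and cardiometabolic
    disease prevalence, with interquartile effect scaling, quantile
    regression, generalized additive model, county-aggregation and
    spatial-error sensitivity analyses. Includes a gravity-model synthetic
    study generator with planted coefficients so every pipeline stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    foreign,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
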