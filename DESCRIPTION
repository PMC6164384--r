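Package: nmrqsar
Title: NMR Spectral Binning and QSAR Modeling for Natural-Product
    Anticancer Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns one-dimensional 1H and 13C NMR peak lists of
    natural-product crude extracts, fractions and pure compounds into
    fixed-width chemical-shift-bin descriptor matrices and models
    anticancer activity classes (HCT116 IC50 thresholds) with random
    forests, k-nearest neighbours and support vector machines.  Also
    provides the supporting QSAR machinery used for molecular-descriptor
    regression workflows: Kohonen self-organizing maps for chemistry-aware
    train/test partitioning and a response-pattern applicability domain,
    correlation-based feature selection (CFS), M5-style stepwise
    descriptor elimination with AIC stopping, top-N selection by random
    forest permutation importance, the full evaluation metric suite
    (sensitivity, specificity, overall accuracy, G-mean, squared Pearson
    R2, RMSE, MAE, outlier rules), IC50/pIC50 transforms, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
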