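Package: covbat
Title: Harmonization of Mean, Variance, and Covariance Site Effects in
    Multi-Site Feature Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements CovBat harmonization for multi-site studies of
    continuous derived measurements such as regional cortical thickness.
    CovBat first applies the ComBat empirical-Bayes location-scale model
    to remove per-feature site effects in mean and variance, then
    harmonizes the covariance structure by matching per-site means and
    variances of principal-component scores of the pooled residuals.
    The package also provides a synthetic multi-site data generator with
    configurable mean, variance, and covariance site effects, and an
    evaluation harness quantifying residual site effects via covariance
    Frobenius distances, random-forest site and diagnosis detection AUC,
    and MANOVA with Pillai's trace.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
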