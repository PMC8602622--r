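Package: aerometab
Title: Two-Factor Metabolomics Analysis of Intrinsic Aerobic Capacity and Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for targeted metabolomics studies with a
    two-factor (intrinsic aerobic capacity x age) design across multiple
    tissues. Provides per-metabolite Box-Cox transformation selected under a
    design-residual skew/kurtosis criterion with unit-variance scaling,
    NIPALS partial least squares discriminant analysis with cross-validated
    Q2, variable importance in projection (VIP) and label-permutation
    validation, per-metabolite two-factor interaction regressions with joint
    F-tests, running-speed association screening with Benjamini-Hochberg
    false discovery rate control, Venn partitioning of significant
    metabolites with coefficient-sign directions, hypergeometric pathway
    over-representation analysis against user-supplied GMT libraries, and a
    synthetic-data generator emulating the factorial study design with known
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
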