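Package: trialmnar
Title: Missing Outcomes and Incomplete Intervention Uptake in Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequences of randomisation-based analyses for two-follow-up
    randomised trials with missing outcome data and incomplete uptake of the
    intervention. Implements complete-case regression, linear generalised
    estimating equations, bivariate normal mixed models with per-arm
    covariances, multiple imputation by chained equations with predictive
    mean matching and Rubin's-rules pooling, pattern-mixture sensitivity
    analysis indexed by arm-specific informative-missingness offsets, a
    repeated-contact-attempts selection model fitted by full maximum
    likelihood with Gauss-Hermite quadrature, and structural mean models
    estimated by instrumental variables with inverse-probability-weighting,
    adjusted-treatment-received and multiple-imputation corrections for
    missing outcomes. Includes a synthetic trial generator emulating an
    Internet-based alcohol-reduction trial so that every estimator can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
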