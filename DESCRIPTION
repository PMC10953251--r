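Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection and LD clumping, effect-allele
    harmonization with palindromic-variant handling, instrument-strength
    diagnostics (variance explained and F statistics), five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode, simple mode), sensitivity analyses (Cochran's Q,
    MR-Egger intercept, leave-one-out, MR-PRESSO style outlier detection),
    multivariable MR, and two-step mediation decomposition of total effects
    into direct and indirect components. Includes a synthetic GWAS
    summary-statistic generator with known causal structure for validating
    every stage of the workflow, and a pipeline for bidirectional
    exposure-outcome studies with mediator screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
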