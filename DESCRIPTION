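Package: somnimr
Title: Two-Sample Mendelian Randomization and Genetic-Overlap Analysis from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete summary-statistics causal-inference workflow for
    epidemiological studies: instrument selection by LD clumping with proxy
    search, allele harmonization with palindromic-variant filtering, five
    univariable two-sample Mendelian randomization estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode,
    robust adjusted profile score) with a full sensitivity suite (Cochran's Q,
    Egger intercept, MR-PRESSO outlier detection, Steiger directionality,
    leave-one-out), multivariable MR with adjusted heterogeneity diagnostics,
    two-step mediation by the product-of-coefficients method, bivariate LD
    score regression for genetic correlation, and conjunctional FDR for
    shared-locus discovery. Includes a synthetic GWAS summary-statistics
    generator with known ground truth so the whole pipeline can be run and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
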