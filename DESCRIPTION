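Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (genome-wide significance,
    LD clumping, confounder filtering, F-statistics), allele harmonization
    with palindromic-variant handling, five causal-effect estimators
    (inverse-variance weighted, weighted median, MR-Egger, maximum
    likelihood, robust adjusted profile score), a sensitivity suite
    (Cochran's Q, Egger intercept, leave-one-out, funnel data, MR-PRESSO
    outlier detection), and two-step mediation MR with the mediated
    proportion computed by the product method. Includes a summary-statistic
    simulator with configurable pleiotropy and block LD so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
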