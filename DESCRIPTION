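Package: mrmediate
Title: Two-Sample and Two-Step Multivariable Mendelian Randomization with
    Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, F-statistic grading), allele
    harmonization with palindromic-SNP handling, causal-effect estimation
    (Wald ratio, inverse-variance weighted, MR-Egger, weighted median),
    sensitivity diagnostics (Cochran's Q, Egger intercept, leave-one-out,
    MR-PRESSO outlier detection), multivariable MR, two-step MR mediation
    analysis with proportion mediated, analytic power calculations for
    binary outcomes, and a synthetic summary-statistics generator with
    known causal structure for validating every stage without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
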