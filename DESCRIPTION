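Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: reading and validating summary-statistic
    tables, instrument selection (p-value thresholding with fallback, greedy
    LD clumping, variance explained and F-statistics, weak-instrument
    exclusion), exposure/outcome allele harmonization including
    frequency-based resolution of palindromic variants, closed-form causal
    estimators (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median with bootstrap standard errors), sensitivity analysis (Cochran's
    Q, Egger intercept, leave-one-out), Bonferroni multiplicity control and
    a three-criterion robust-inference decision rule, orchestrated over
    exposure-by-outcome grids. A seeded synthetic summary-statistics
    generator with known causal effects, pleiotropy architectures, LD
    blocks, palindromes and strand flips supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
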