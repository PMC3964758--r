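Package: twinmet
Title: Family-Based Candidate-Gene Association Analysis of Leisure-Time
    Exercise Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-gene association studies of leisure-time
    exercise behavior in twin-family samples. Scores weekly MET hours from
    exercise-activity questionnaires with regularity filtering, truncation
    and longitudinal merging; codes SNP and VNTR genotypes and applies
    standard quality control (minor allele frequency, Hardy-Weinberg
    equilibrium, Mendelian consistency, call rate, concordance); fits
    maximum-likelihood linear mixed models with an additive-genetic
    relationship-matrix random effect for single-variant, joint and
    polygenic-risk-score tests; and estimates statistical power by
    Monte-Carlo simulation with gene dropping through synthetic twin-family
    pedigrees and truncated, familially correlated phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
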