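Package: endoscore
Title: Multivariate Neuroanatomical Endophenotype Scores and Candidate-Region Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a disease-discriminative neuroanatomical score from
    high-dimensional brain morphometry with a penalized logistic discriminant,
    and uses the score as a quantitative endophenotype for candidate-region
    genetics: per-cohort SNP association, inverse-variance-weighted
    fixed-effects meta-analysis with Bonferroni correction, posterior
    fine-mapping of causal configurations from Z-scores and linkage
    disequilibrium, quantile-quantile enrichment comparison with
    order-statistic envelopes, and SNP-heritability estimation by restricted
    maximum likelihood on a genetic relationship matrix. Includes a
    multi-cohort synthetic-data generator with planted effects so the whole
    pipeline is testable without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
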