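Package: rarelasso
Title: LASSO-Collapsed Rare-Variant Composite Markers with Tree-Ensemble
    Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Collapses rare genetic variants into non-rare composite markers
    and tests them for case-control association. Rare variants passing minor
    allele frequency and Hardy-Weinberg quality filters are grouped by gene
    or by chromosomal position; within each group an L1-penalized logistic
    regression with unpenalized covariates is fitted along the full
    regularization path, the Akaike information criterion picks the penalty,
    and the fitted linear combination of carrier indicators becomes a
    composite marker if it is nonzero in enough subjects. Markers are then
    evaluated by classification-tree analyses across phenotype replicates,
    and marker significance is declared against a binomial split-frequency
    null with Bonferroni correction, with a permutation-based alternative.
    Includes a synthetic cohort generator for unrelated case-control data
    with a rare-skewed allele frequency spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    rpart,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
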