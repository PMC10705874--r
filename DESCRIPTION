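Package: radinject
Title: Reliability of Radiomics Feature Selection Under Irrelevant-Feature Injection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stress-test radiomics-style classification pipelines by
    progressively injecting randomly generated irrelevant features into a
    feature table and measuring the consequences. The package generates
    synthetic radiomics-like tables with a known informative subset, fabricates
    uniform random features whose ranges mimic randomly picked real features,
    runs Mann-Whitney filtering followed by MRMR, random-forest RFE or LASSO
    feature selection, fits random-forest and L1-penalized logistic-regression
    classifiers under stratified cross-validation with minority oversampling,
    and summarises selection contamination, multi-set Jaccard stability,
    hold-out performance, and normalized feature importance across injection
    levels, with one-way ANOVA and Bonferroni-corrected comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
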