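Package: scDEbench
Title: Benchmarking Differential Expression Workflows for Multi-Batch
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-batch single-cell RNA-seq count data with known
    differential-expression ground truth using either a negative-binomial
    model with logistic dropout or binomial downsampling of real counts,
    runs native differential-expression procedures (Wilcoxon rank-sum,
    batch-covariate negative-binomial regression, pseudobulk tests and
    per-batch meta-analysis combiners), ingests externally computed result
    tables, and scores workflows with precision-weighted F-scores, partial
    areas under the precision-recall curve, sign error ratios, angular
    logFC distortion, weighted cumulative disease-gene scores and a
    truncated weighted Kolmogorov-Smirnov test, together with rule-based
    Good/Intermediate/Poor performance grading and principal variance
    component analysis of batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    lme4,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
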