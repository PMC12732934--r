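Package: onsetomics
Title: Transcriptomic Age-of-Onset Analysis for Bipolar Disorder and Schizophrenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying age-of-onset effects in
    postmortem brain transcriptomes of bipolar disorder and schizophrenia.
    Provides a synthetic cohort generator with planted effect structure,
    expression filtering and normalization with precision weights,
    empirical-Bayes batch adjustment, covariate-adjusted per-gene onset
    models (primary, sex-stratified and onset-by-diagnosis interaction
    designs) with moderated inference, preranked gene-set enrichment with a
    permutation null, signed weighted co-expression networks with
    topological overlap and module eigengenes, marker-gene relative
    cell-type proportion estimation, a repeated nested cross-validation
    two-stage early-onset classifier with LASSO stability selection, and a
    two-cohort signed meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    fgsea,
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
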