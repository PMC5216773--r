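Package: fmlncsim
Title: Fuzzy-Measure Disease Semantic Similarity and lncRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes disease semantic similarity from MeSH Category C
    descriptor hierarchies using information content combined with Sugeno
    lambda fuzzy measures, lifts it to lncRNA functional similarity through
    best-match comparison of associated disease groups, and scores candidate
    lncRNA-disease associations with a two-space Laplacian-regularized
    least-squares classifier over integrated similarity matrices (semantic,
    functional, Gaussian interaction-profile kernel, and optional expression
    similarity). Includes global leave-one-out and repeated k-fold
    cross-validation with ROC/AUC summaries, per-disease candidate ranking,
    and a seeded generator of synthetic MeSH-like forests and block-structured
    association matrices for fully offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dag.R'
    'evaluate.R'
    'fmlncsim-package.R'
    'functional.R'
    'fuzzy.R'
    'io.R'
    'kernels.R'
    'lrls.R'
    'mesh.R'
    'simulate.R'
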