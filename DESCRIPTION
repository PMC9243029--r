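Package: pipespace
Title: Guided Multiverse Analysis of Connectivity Pipelines via Active Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds a combinatorial space of connectivity-analysis pipelines
    into a low-dimensional space via between-participant similarity signatures,
    then searches it with Gaussian-process Bayesian optimisation using an
    upper-confidence-bound acquisition whose kappa parameter trades off
    mapping the whole space against racing to an optimal pipeline. Includes a
    seeded synthetic-cohort generator (planted target signal in region
    couplings, multiple correlated preprocessing variants), pipeline grids for
    a regression design (data variant x proportional threshold x nodal graph
    metric) and a classification design (preprocessing x strategy x
    parcellation x connectivity estimator), cosine-similarity pipeline
    signatures, metric MDS and PCA embeddings with a neighbourhood-preservation
    score, cross-validated pipeline evaluation, exhaustive landscapes,
    repeated-run reliability reports and lock-box hold-out scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
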