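Package: speechscca
Title: Sparse Canonical Correlation Analysis Linking Speech Features to
    Clinical and Brain Imaging Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline relating automatically derived linguistic
    features of interview transcripts to clinical symptom scores and to brain
    structural and resting-state functional-connectivity measures.  Extracts
    amount-of-speech statistics, latent-semantic-analysis coherence of
    consecutive sentences, and Penn Treebank part-of-speech tag frequencies
    from raw transcripts; computes within-network cohesiveness and hub-centred
    network integration from node time series; harmonizes imaging feature
    matrices across acquisition sites with parametric empirical-Bayes ComBat;
    and fits sparse canonical correlation models by penalized matrix
    decomposition with sparsity chosen by grid search and significance
    assessed by a permutation test against the null distribution of maximal
    canonical correlations.  A synthetic-data module generates transcripts,
    time-series panels, morphometry tables and linked feature blocks with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
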