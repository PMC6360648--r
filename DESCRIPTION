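Package: genevec
Title: Distributed Gene Representations from Co-Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns dense vector representations of genes from gene
    co-expression pair corpora with a skip-gram model trained by negative
    sampling (an exact full-softmax mode is provided for small vocabularies).
    Expression matrices are log-transformed, quantile-normalized and collapsed
    to one maximum-variance probe per gene; gene pairs with Pearson
    correlation at or above a threshold form the training corpus. Embedding
    hyperparameters are tuned by pathway clusteredness (the ratio of mean
    within-pathway inner product to the mean inner product of random gene
    pairs), embeddings are visualized as 2-D co-expression maps via PCA and
    t-SNE with optional tissue-specificity z-score overlays, and embeddings
    feed a gene-pair functional-interaction classifier evaluated under
    gene-disjoint train/validation/test splits. A planted-module simulator
    generates synthetic compendia, pathway files and annotation tables so the
    whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    limma,
    fgsea,
    igraph,
    Rtsne,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    rhdf5,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
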