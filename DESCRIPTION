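Package: sctransfer
Title: Transfer Learning for Single-Cell RNA-Seq Clustering via NMF Dictionaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves the clustering of small single-cell RNA-Seq datasets by
    transferring knowledge from a large, well-annotated reference dataset.
    A gene-by-cluster dictionary is learned from the labeled source expression
    matrix by elastic-net regularized non-negative matrix factorization (NMF),
    transferred to the unlabeled target through non-negative least squares,
    and blended with the original target matrix through a convex mixture whose
    weight is selected automatically by kernel target alignment. The modified
    target is clustered with an SC3-style consensus clusterer. Includes a
    hierarchical negative-binomial count simulator, TargetCluster and
    ConcatenateCluster baselines, and an adjusted-Rand-index evaluation
    harness with repetition-level confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
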