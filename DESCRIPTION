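Package: netimpute
Title: Network-Based Dropout Imputation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes dropout events in single-cell RNA-seq expression
    matrices by diffusing expression values over a gene (or cell)
    co-expression network. The network is built by mutual k-nearest
    neighbors on Pearson similarity (or taken from a confidence-filtered
    protein-protein interaction table), diffusion uses the stationary
    distribution of a random walk with restart, and each value is replaced
    by the outgoing-probability-weighted average of its network
    neighborhood. Ships a zero-inflation simulator and a PCA+k-means /
    adjusted Rand index evaluation harness so the method can be assessed
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
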