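Package: statepath
Title: Cell-State Transition Networks from Time-Series Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers transcriptomic cell states and their transitions from
    time-series gene-expression data alone. Genes are clustered on their
    temporal profiles, the number of clusters is selected by a gap statistic
    whose dispersion is the summed Gaussian-process log marginal likelihood
    of cluster members, each cluster is summarised by a Gaussian-process
    regression (RBF plus white-noise kernel), and the clusters are ordered
    into a directed state-transition path using shape-based distance
    (maximal normalised cross-correlation over integer shifts) combined with
    the ranked-pairs tournament algorithm. Adjacent states are annotated
    with biological pathways through a two-group hypergeometric enrichment
    test. Includes a synthetic-data generator with planted cluster
    structure, temporal shifts and pathway memberships, plus standard
    clustering quality metrics (pair-based F1, adjusted Rand index,
    silhouette, completeness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
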