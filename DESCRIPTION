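Package: intervalmix
Title: Co-Occurrence Clustering of Genomic Interval Tracks with Bernoulli Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters genomic regions of interest by the joint
    presence/absence pattern of multiple genomic-interval tracks (for
    example ChIP-seq peak lists in BED format). Regions are summarized as
    a binary overlap matrix and modelled with a finite mixture of
    products of Bernoulli distributions, fitted by an EM algorithm with
    K-means initialization. The number of clusters is chosen by BIC or by
    the elbow of the log-likelihood curve. Fitted mixing proportions and
    occurrence probabilities act as sufficient statistics: any joint or
    conditional occurrence probability over a subset of tracks can be
    queried from the parameters alone. Includes cluster-versus-feature
    overlap summaries with length-based expected baselines, a synthetic
    data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    withr,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
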