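Package: multihic
Title: Multipartite Bacterial Genome Hi-C, ChIP Enrichment, and Origin-Focus Analysis
Version: 0.1.0
Authors@R:
    person("multihic", "developers", email = "multihic@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the organization of multipartite bacterial
    genomes, modeled on the four-replicon genome of Agrobacterium tumefaciens
    (circular chromosome 1, linear chromosome 2, plasmids pAt and pTi). Builds
    binned Hi-C contact matrices from contact records, balances them by
    iterative correction, and quantifies inter-replicon interactions (origin
    clustering and lengthwise chromosome alignment) as percentages relative to
    a wild-type reference after background subtraction. Also computes ChIP/input
    enrichment tracks with peak quantification, and single-cell origin-focus
    statistics (focus counts, colocalization at a pixel-distance threshold,
    distance to the nearest cell pole). A synthetic-data module generates
    contact maps, contact records, ChIP/input tracks and per-cell focus tables
    with the statistical structure the analysis assumes, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
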