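Package: netwalk
Title: Data-Biased Random Walks for Context-Specific Network Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every node and every interaction of a molecular
    interaction network by the joint coherence of experimental data values
    (strictly positive ratios, e.g. treated/control expression changes) and
    local network connectivity.  A random walk with restart is biased by the
    data both in its transition probabilities and in its restart
    distribution; stationary visitation frequencies and per-interaction
    Edge Flux values are normalized against a topology-only background walk
    so that hub bias is removed.  Includes construction of
    functional-similarity edges from annotation overlap, extraction of
    high- and low-scoring subnetworks, Ward clustering of Edge Flux values
    across conditions, data/network perturbation experiments, and fully
    seeded synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
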