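Package: scgraft
Title: Reference Mapping of Single-Cell Atlases by Architecture Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds integrated single-cell RNA-seq reference atlases with
    conditional (variational) autoencoders and maps new query studies onto a
    frozen reference by "architecture surgery": per-study adaptor weight
    vectors are grafted into the first encoder and decoder layers and are the
    only parameters trained, so a query can be integrated without touching the
    reference model or data. Supports Gaussian, negative binomial and
    zero-inflated negative binomial likelihoods, an optional maximum mean
    discrepancy penalty between studies, weighted k-nearest-neighbour label
    transfer with uncertainty-based rejection of unseen cell types, a
    ten-metric integration-quality suite (batch mixing entropy, silhouette
    scores, NMI, ARI, principal-component regression, graph connectivity,
    isolated-label scores, kNN accuracy), and a seeded synthetic atlas
    generator with hold-out-cell-type experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
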