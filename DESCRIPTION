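Package: vesseltrace
Title: Tracing Retinal Vessel Trees by Graph-Based Label Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates a retinal vessel network into its constituent rooted
    trees starting from a binary vessel segmentation. The mask is reduced to a
    classified one-pixel skeleton with per-point radii, vessel segments become
    nodes of an undirected dual graph, segments are ordered by a modified
    Shreve scheme that handles crossovers, the graph is simplified per
    junction clique, an orientation-based affinity matrix is assembled, and
    tree labels are propagated from root segments by transductive label
    propagation. Includes a seeded synthetic vascular-scene generator with
    ground truth, a segmentation-fusion and branch-reconnection toolkit, SWC
    export, and a segment-level evaluation proxy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    methods,
    EBImage,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
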