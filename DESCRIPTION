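Package: netrsa
Title: Layer-Activation Extraction and Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts activations from named modules of layered neural
    networks for ordered image datasets and compares the resulting
    representations with representational similarity analysis (RSA).
    Provides a deterministic pure-R inference engine with an architecture
    registry (canonical AlexNet and a small test network), period-addressed
    module selection, batched forward passes, flattening of K x H x W
    activations into feature matrices with row-order provenance, persistence
    in npy/txt/mat/hdf5 formats with k-way splitting and merging,
    representational dissimilarity matrices under euclidean, correlation,
    cosine and gaussian metrics, RDM comparison on upper triangles, heat-map
    plotting with cluster-based reordering, and seeded generators for
    synthetic image sets and structured feature matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    jpeg,
    tiff,
    rhdf5,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
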