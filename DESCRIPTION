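Package: mogfuse
Title: Multi-Omics Cancer Subtype Classification via Graph Convolution,
    Similarity Network Fusion and Graph Attention
Version: 0.1.0
Authors@R:
    person("Maintainer", "mogfuse", email = "maintainer@mogfuse.org",
           role = c("aut", "cre"))
Description: Two-stage multi-omics subtype classifier for patient cohorts.
    Stage one learns supervised per-omics latent embeddings with graph
    convolutional networks trained on scaled-exponential-kernel patient
    affinity graphs, sparsified by a dynamic edge-retention threshold that
    keeps the smallest top-percentile of edges yielding a full-rank degree
    matrix. Stage two fuses the per-omics affinity networks with similarity
    network fusion (cross-diffusion) and classifies subtypes with a two-head
    graph attention network over the fused patient graph. Includes a seeded
    synthetic multi-omics generator, stratified splitting, macro-averaged
    evaluation metrics, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
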