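Package: histex
Title: Reconstructing Spot-Resolved Tumor Gene Expression from H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for learning the link between H&E histological morphology and
    spatially resolved gene expression on hexagonally arranged spatial
    transcriptomics arrays (10x Visium dialect). Transforms hexagonal spot
    lattices into dense grids that preserve relative spot proximity, selects
    spatially variable target genes by Moran's I with k-nearest-neighbour
    binary weights, crops and featurises spot-centred image patches, trains a
    five-level convolutional encoder-decoder with multi-scale attention-gated
    skip connections and a ConvMixer bottleneck to segment tumor regions and
    regress spot-resolved expression, and drives downstream survival
    (Cox partial likelihood) and immunotherapy-response heads on a
    ConvNeXt-V2-style backbone. Includes segmentation, correlation, concordance
    and Kaplan-Meier/log-rank evaluation utilities and a fully seeded synthetic
    data generator emulating spot tables, counts, images and clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    tiff
Config/testthat/edition: 3
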