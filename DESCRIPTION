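Package: pgkernel
Title: Perceptual Graph Kernels for Image-Derived Plant Stress Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes image-derived plant traits as perceptual intensities and
    discrete states, builds deviation-weighted trait-interaction graphs, and
    compares plants through graph kernels: a Gaussian or linear kernel on a
    fixed-order edge-deviation embedding, plus Weisfeiler-Lehman subtree and
    shortest-path baselines. Provides precomputed-kernel support vector machine
    classification of plant stress with stratified cross-validation and grid
    search, zone-level similarity staging of field health (Healthy / Mild
    Stress / Severe Stress), a calibrated synthetic multi-acre field generator,
    and trait extraction from RGB plant images (excess-green segmentation,
    morphology, grey-level co-occurrence texture).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    methods,
    kernlab,
    igraph,
    jsonlite,
    xml2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    pheatmap,
    optparse
Config/testthat/edition: 3
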