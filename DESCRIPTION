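Package: morphoprop
Title: Semi-Supervised MRI Classification by Label Propagation on
    Voxel-Based Morphometry Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-based semi-supervised classification of structural
    brain MRI. Extracts voxel-based-morphometry-style features from
    registered gray-matter probability volumes (group mask, isotropic
    Gaussian smoothing, voxelwise two-sample t-maps, connected
    suprathreshold clusters), reduces them by PCA with a
    cumulative-energy rule, builds a Gaussian-kernel affinity graph with
    a column-normalized transition matrix, and propagates clamped
    diagnostic labels to unlabeled subjects by the iterative algorithm
    or its closed-form harmonic solution. Includes synthetic cohort
    generators, cross-validation of the kernel bandwidth, and a
    repeated-random-split evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
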