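Package: synaptrack
Title: Vesicle-Microcluster Dynamics from Multi-Channel Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation, tracking and interaction statistics for signaling
    microclusters and trafficking vesicles imaged at the immunological synapse.
    Provides spot/surface detection by band-pass enhancement and thresholding,
    greedy nearest-neighbour tracking with gap closing, object-based dynamic
    colocalization with per-track lifetime-contact fractions and a Costes
    block-randomization null, anisotropic distance-transform proximity
    kinetics, coincident two-channel intensity flare detection, fixed-cell
    cluster statistics and line-scan profiles, and a synthetic two-phase
    synapse simulator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
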