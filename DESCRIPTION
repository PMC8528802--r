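Package: qtimap
Title: Quantitative Transient-State MRI Simulation, Reconstruction and Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and analysis pipeline for 3D quantitative
    transient-state imaging (QTI), an MR-fingerprinting-style method for
    simultaneous T1, T2 and proton-density mapping. Provides an extended
    phase graphs (EPG) signal simulator for inversion-prepared ramped
    flip-angle gradient-spoiled sequences, dictionary generation on a
    (T1, T2) grid with SVD temporal subspace compression, dictionary
    matching and compact neural-network parameter inference, undersampled
    spiral k-space acquisition simulation with exact non-uniform Fourier
    sampling, zero-filled, view-shared and low-rank plus total-variation
    (LRTV) reconstruction, synthesis of T1-weighted, T2-weighted and FLAIR
    contrasts from the quantitative maps, a seeded digital brain-tumor
    phantom, and ROI statistics with two-component Gaussian-mixture
    subclassification of tumor voxels in the T1-T2 plane.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
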