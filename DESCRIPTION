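Package: connectograd
Title: Connectopic Gradient Mapping and Seed Connectivity for fMRI Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers the dominant modes of functional-connectivity change
    (connectopic gradients) within a region of interest from 4D BOLD fMRI:
    voxel-wise connectivity fingerprints against an SVD-reduced
    representation of the rest of gray matter, eta-squared similarity,
    Laplacian Eigenmaps, topology-preservation scoring and median-split
    parcellation. Also provides model-based seed connectivity (SVD
    representative time series, partial correlations with Fisher-Z,
    seed-pair GLM maps, sign-flip permutation inference), motion-derived
    quality control (framewise displacement, scrubbing, participant
    exclusion), SNR estimation, a canonical-HRF stimulus GLM, and a
    synthetic-data generator with known ground-truth gradients so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
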