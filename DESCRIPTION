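Package: glimquant
Title: Quantitative Phase Reconstruction and Single-Cell Dry-Mass
    Densitometry for Gradient Light Interference Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gradient light interference microscopy (GLIM) of
    thick scattering specimens such as acute brain slices: a forward
    optical simulator producing four-frame phase-shifted interferogram
    z-stacks from refractive-index phantoms with known ground truth;
    four-step phase-shifting retrieval of the lateral phase gradient and
    mutual intensity; Hilbert-transform (spectral) integration to
    quantitative phase tomograms; 3D single-cell segmentation from sparse
    per-slice ROI traces via Delaunay-hull voxelization refined by the
    phase signal; per-cell volume, dry mass (refractive increment
    alpha = 0.2 mL/g), density, and damaged-cell detection; and nested
    day-versus-night group statistics (exact Mann-Whitney and mixed-model
    ANOVA with animal as a random factor), including the volume-mass
    regression and its implied mass density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    tiff,
    EBImage,
    lme4,
    lmerTest,
    emmeans,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
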