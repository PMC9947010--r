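Package: smlmtools
Title: Localization Microscopy Post-Processing, Single-Particle Mobility and
    Tessellation-Based Co-Localization
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule localization microscopy
    (SMLM/STORM) and single-particle tracking (SPT) of cell-surface
    molecules. Provides localization-table input/output (ThunderSTORM-dialect
    CSV), sigma filtering, frame-consecutive grouping, drift estimation and
    correction (fiducial-based and image cross-correlation), two-channel
    registration and affine chromatic-aberration correction, and Fourier
    ring correlation resolution estimation. Implements track linking,
    per-track mean jump distance (MJD), two-Gaussian mixture decomposition
    of MJD histograms with the high-mobility area fraction (R-value),
    Voronoi-tessellation density mapping with cluster segmentation and
    equivalent-circle diameters, coordinate-based Spearman and Manders
    co-localization with even/odd-frame positive and vertical-flip negative
    controls, confocal foci-density quantification and the phagocytic index.
    A synthetic-data module generates Brownian track sets, blinking
    clustered emitters, drift, fiducials and paired channels with ground
    truth so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
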