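Package: stain3d
Title: Chromogenic Stain Segmentation, Left/Right Morphometry and 3D
    Reconstruction of Serial Histology Sections
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying chromogenic (X-gal, blue) staining in
    serial color histology sections of the mouse heart. Segments
    stain-positive pixels by k-means clustering in CIE L*a*b* color space,
    quantifies left/right asymmetry of positive pixels about an operator
    (or phantom ground-truth) apex-to-base separation line with per-heart
    mean +/- SEM summaries and two-sample t-tests, rigidly registers
    consecutive sections, stacks them with a slice-thickness replication
    factor into a binary voxel volume, and exports MetaImage (.mhd/.raw)
    volumes with orthogonal maximum-intensity projections. Includes a
    synthetic serial-section phantom generator with exact ground truth
    (stain masks, separation line, left-side fraction, inter-slice rigid
    transforms) so the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
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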