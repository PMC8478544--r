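Package: aortamorph
Title: Segmentation and Quantification of Atherosclerotic Plaque in
    Contrast-Enhanced MicroCT of Mouse Aortas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semiautomatic workflow for segmenting the aortic wall, lumen,
    atherosclerotic plaques, and plaque-wall contact lesions in
    contrast-enhanced (phosphotungstic acid stained) microCT volumes of
    mouse aortas, and for quantifying plaque burden. Sparse manual outer
    contours are interpolated into a dense region of interest by
    signed-distance blending; wall and lumen are segmented by dual
    attenuation thresholds with morphological closure of branch ostia and
    under-stained wall; plaques are extracted inside the lumen by Gaussian
    smoothing, thresholding, and opening/closing refinement; lesions are
    the plaque voxels in contact with the wall. Outcomes include volumes by
    voxel counting, surfaces by iso-surface triangulation, local wall
    thickness by a distance-transform inscribed-sphere algorithm, per-slice
    stenosis and lesion length, and Bland-Altman/linear-model method
    agreement. A parametric synthetic aorta phantom with analytic ground
    truth replaces scanner data for testing and validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
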