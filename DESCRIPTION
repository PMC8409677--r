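Package: pollenmorph
Title: Pollen Grain Morphometry and Taxon Classification from Multi-Focal-Plane Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automated melissopalynology by image analysis: synthetic
    pollen phantom generation across bright-field, dark-field and
    phase-contrast modalities, RGB threshold segmentation with morphological
    post-processing, extended-depth-of-focus reconstruction from five-plane
    focal stacks, a 30-descriptor morphological/volumetric/colour/EDF feature
    vector per grain, per-descriptor Tukey HSD compact-letter grouping, factor
    analysis with an eigenvalue/max-correlation retention rule, and linear
    discriminant classification of seven honey pollen taxa with confusion
    matrices and correct classification rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
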