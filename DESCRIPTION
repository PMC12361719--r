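Package: mtlseg
Title: Landmark-Based Segmentation Protocol for Anterior Medial Temporal
    Lobe Cortices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives and applies an anatomically grounded, landmark-based
    segmentation protocol for the anterior entorhinal cortex (ERC) and
    Brodmann areas 35 and 36 on coronal sections of the medial temporal
    lobe. Provides arc-length geometry on coronal pial contours,
    computation of protocol landmarks (parahippocampal gyrus edges and
    crown, collateral sulcus banks and fundus, fusiform crown), a seeded
    synthetic phantom cohort generator, signed border-to-landmark distance
    measurement, derivation of slice-wise placement rules (anchor
    selection, grid quantization, offset rounding), a deterministic
    rule-based segmentation engine producing interval label maps with
    optional rasterization, and reliability evaluation with the Dice
    Similarity Index including landmark-perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    RNifti,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'landmarks.R'
    'ruletable.R'
    'contour-builder.R'
    'cohort.R'
    'measurement.R'
    'derivation.R'
    'segmentation.R'
    'raster.R'
    'evaluation.R'
    'io.R'
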