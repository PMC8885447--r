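Package: inclusionprofiler
Title: High-Content Profiling of Protein Inclusion Phenotypes in
    Fluorescence Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline from two-channel (nuclear dye + GFP) multi-field
    plate images to per-well percentages of transfected cells bearing
    protein inclusions, via illumination correction, nucleus-seeded cell
    segmentation within a size gate, per-cell cytoprofiles (intensity,
    shape, Haralick texture, granulometry, radial intensity
    distribution) and user-assisted random-forest classification.
    Downstream drug-combination analytics: highest-single-agent (HSA)
    checkerboard synergy scoring, live-cell relative-survival curves
    with trapezoid AUC, and four-parameter logistic dose-response fits.
    A synthetic plate simulator emits ground-truthed images, masks and
    labels so every stage is verifiable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    randomForest,
    minpack.lm,
    pracma,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
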