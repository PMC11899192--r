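Package: fibmorph
Title: Cross-Sectional Fibular Bone Morphometry from MRI Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures cortical bone geometry of the fibula from cross-sectional
    MR images and binary segmentation masks: bone area, medial-axis centerline
    length, ring-model wall thickness (area divided by centerline length),
    the inner-to-outer-diameter g-ratio, a normalized mean-pixel-intensity
    index of mineral density loss, and bone marrow area, averaged over the
    central slices of a multi-slice stack. Includes a synthetic annular
    phantom generator with analytic ground truth, a cohort simulator with
    configurable age and sex effects, the study-level statistical battery
    (two-sample t-tests, linear correlations, muscle-fat-infiltration
    contrasts, segmentation-noise robustness), and an end-to-end synthetic
    study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
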