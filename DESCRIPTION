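Package: cariometry
Title: Lesion Activity Assessment from Dehydration, OCT and MicroCT Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the activity of (secondary) caries lesions from
    image time series acquired while a tooth surface is dried with forced
    air. Computes integrated shortwave-infrared (SWIR) reflectance change
    and integrated evaporative-cooling statistics for lesion and control
    regions of interest, measures lesion depth, integrated reflectivity
    and transparent-surface-layer thickness from optical coherence
    tomography B-scans (with refractive-index depth correction), measures
    lesion depth and surface-layer thickness from micro-computed
    tomography slices via median smoothing, Sobel edge detection and line
    profiles, and joins the per-lesion measurements into correlation,
    threshold-split and activity-classification analyses. A synthetic
    cohort generator renders all four modalities from ground-truth lesion
    parameters so that every analysis stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
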