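Package: lgescar
Title: Automatic Quantification and Localization of Ischemic Scars in
    Late Gadolinium-Enhancement Cardiac MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of short-axis late gadolinium-enhancement
    cardiac magnetic resonance (LGE-CMR) studies with manually annotated
    endocardial and epicardial contours. Builds a polar parameterization
    of the left-ventricular myocardium (angular phase and normalized
    radial wall position), segments scar tissue by the full-width-half-max
    (FWHM) criterion against the study-wide maximum signal intensity,
    extracts connected scar segments, and quantifies scar size, angular
    (endocardial) extent, transmurality and scarring fraction. Scar
    sectors are localized on the 16 in-plane segments of the AHA
    17-segment model and can be aggregated per infarct-related artery
    across a cohort. A synthetic phantom generator renders annular
    myocardium with bright scar sectors of known geometry so that every
    stage is testable without patient data. Includes a minimal DICOM
    reader/writer for uncompressed explicit-VR little-endian grayscale
    series and a JSON sidecar format for contour annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
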