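Package: claustrseg
Title: Landmark-Based Automatic Segmentation of the Dorsal Claustrum from High-Resolution MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the human dorsal claustrum from high-resolution T1-weighted
    MRI using anatomical landmarks: the lateral edge of a putamen mask is expanded
    laterally toward the insula, voxels near cerebrospinal fluid are excluded,
    two-cluster intensity clustering separates the claustrum from surrounding white
    matter, and per-sagittal-slice smoothing yields a continuous sheet. Also
    provides the Dice overlap coefficient, mask volume, regional means of scalar
    maps, mean diffusivity from a log-linear diffusion tensor fit, across-subject
    structural-covariance networks with multiple-comparison correction, a
    deterministic synthetic phantom and cohort generator for end-to-end testing
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    tibble,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
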