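Package: htmotion
Title: Hierarchical Template Matching for Cardiac Motion and Strain Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-free estimation of myocardial motion from tagged
    short-axis MR image sequences. Dense point correspondences are obtained by
    a hierarchical normalized cross-correlation cascade over nested image
    parts (16/8/4/2 pixel templates with overlapping refinement layers), a
    non-rigid geometric transformation is fitted by the landmark-based Local
    Weighted Mean method (local quadratic polynomials blended by compactly
    supported cubic weights), material points are tracked sequentially over
    the cardiac cycle, and Eulerian (Almansi) circumferential and radial
    strain is reported in the six AHA left-ventricle regions. Includes a
    synthetic tagged-MRI phantom with analytic ground-truth motion and strain
    for validation, and a target-registration-error / model-comparison
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti
Config/testthat/edition: 3
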