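Package: spineval
Title: Preprocessing and Lesion-Wise Evaluation for Whole-Spine Axial T2w
    Spinal Cord MRI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with multi-chunk axial T2-weighted spinal
    cord MRI: stitching independently acquired cervical, thoracic and
    lumbar chunks into whole-spine volumes, invertible spinal-cord
    straightening, region-based overlapping label construction for joint
    cord/lesion segmentation, and a lesion-wise evaluation protocol
    (chunk stacking, connected-component matching at a 10% overlap
    criterion, Dice, normalized surface distance, relative volume error,
    lesion-wise F1 and positive predictive value) with explicit
    empty-mask conventions. Includes a synthetic whole-spine phantom
    generator so every operation can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
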