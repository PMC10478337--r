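Package: atstseg
Title: Semi-Supervised Segmentation of Infected Lung Regions in Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-branch semi-supervised training for segmenting infected lung
    regions (ground-glass opacity and consolidation) in chest CT. Cheap pseudo-labels
    are generated by thresholding Hounsfield units inside a lung mask; a clean branch
    trained on expert labels is coupled to a noisy branch by an adaptive exponential
    moving average, and a Lovasz-extension score automatically switches the noisy
    branch's supervision target from the pseudo-label to the clean branch's own
    prediction once it becomes the more reliable target. Includes NIfTI/DICOM input,
    Dice and 95th-percentile Hausdorff evaluation, infection quantification
    (lung/lesion volumes, GGO vs consolidation split), a compact built-in
    convolutional network engine, and a synthetic CT phantom generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
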