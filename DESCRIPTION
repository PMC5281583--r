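Package: strokeseg
Title: Level-Set Segmentation of Ischemic Stroke Lesions in Mouse Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated segmentation of ischemic stroke lesions in
    quantitative T2 maps of the mouse brain after transient middle cerebral
    artery occlusion. Implements a region-based level-set engine
    (Chan-Vese/Rousson-Deriche energy) with Gaussian and histogram region
    models, atlas label propagation by multi-resolution normalized-correlation
    registration, the four-stage segmentation cascade (whole brain,
    contralateral ventricle, both ventricles, lesion), a semi-automated
    thresholding baseline, agreement metrics (Dice, lesion volume,
    two-way absolute-agreement ICC), and a deterministic synthetic phantom
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
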