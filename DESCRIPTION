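Package: ctastroke
Title: Hemispheric-Comparison 3D Convolutional Detection of Ischemic
    Stroke in CT Angiography Source Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale analysis pipeline for detecting acute ischemic
    stroke lesions in CT-angiography source images with a patch-based,
    dual-pathway (multi-scale) 3D convolutional network. Implements the
    full chain on synthetic head phantoms: phantom cohort generation with
    unilateral hypoattenuated lesions and symmetric aging confounders,
    brain-mask estimation, in-mask intensity standardisation, isotropic
    resampling, construction of a rigidly co-registered left-right
    hemispheric comparison channel, network training with RMSprop and
    Nesterov momentum, tiled whole-volume inference, and two-level
    evaluation: voxel-wise Dice/sensitivity/specificity/ROC and
    ASPECTS-region positivity, contingency metrics and scoring, plus
    largest-connected-component lesion volumetry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'volume-methods.R'
    'evaluate.R'
    'preprocess.R'
    'network.R'
    'phantom.R'
    'pipeline.R'
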