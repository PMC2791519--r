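Package: BMSmaps
Title: Group-Level Bayesian Model Selection Maps for Neuroimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise group-level Bayesian model selection (BMS) from
    per-subject, per-model log-evidence images. Implements the fixed-effects
    group Bayes factor posterior and the random-effects hierarchical
    Dirichlet-multinomial model fitted by variational inference, with
    expected model frequencies and exceedance probabilities, and builds
    thresholded posterior probability maps (PPMs) and exceedance probability
    maps (EPMs) from co-registered NIfTI volumes. Includes a synthetic-data
    generator for the random-effects generative model (including outlier
    groups and spatially structured volume scenarios) so every analysis path
    can be validated without fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
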