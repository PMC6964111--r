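Package: dtigan
Title: Dual Adversarial Harmonization of DTI Scalar Maps Across Imaging Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Removes scanner- and site-related effects from diffusion tensor
    imaging (DTI) scalar maps (fractional anisotropy, mean diffusivity) so
    multi-site cohorts can be pooled. Implements unpaired image-to-image
    translation with two U-Net generators and two Markovian (patch)
    discriminators trained under a Wasserstein objective with gradient
    penalty and an L1 cycle-reconstruction loss, together with the standard
    comparator methods (global-wise scaling, voxel-wise scaling, and
    voxel-level ComBat with optional empirical Bayes shrinkage), evaluation
    statistics (absolute-error maps, RMSE, Cohen's d, along-tract profiles
    with age correlation, voxel-wise permutation group tests), and a
    synthetic phantom-cohort generator with known, invertible site effects
    for end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
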