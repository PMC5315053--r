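Package: hubspoke
Title: Cross-Modal Searchlight MVPA and Resting-State Connectivity for
    Dissociating Input Modality from Amodal Semantic Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a multi-method fMRI analysis
    chain for separating brain regions that code the input modality of
    words (spoken vs written) from regions that code their meaning
    independently of modality, as predicted by the hub-and-spoke model of
    semantic representation.  Provides a synthetic BOLD phantom with
    planted multivoxel condition patterns and seed-anchored resting-state
    networks, block-design GLM fitting with a double-gamma haemodynamic
    response, per-run z-scoring and spherical-searchlight cross-modal
    classification with a linear support vector machine, sign-flip
    permutation group inference with cluster-mass family-wise-error
    correction, a region-by-classifier repeated-measures dissociation
    ANOVA, seed-based functional connectivity with CompCor nuisance
    regression, template-network overlap quantification, and
    meta-analytic spatial-correlation decoding of statistic maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
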