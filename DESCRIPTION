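Package: restdrift
Title: Temporal Drift of Seed-Based Resting-State Connectivity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for quantifying slow temporal drift of
    seed-based whole-brain resting-state functional connectivity patterns
    across densely sampled fMRI sessions. Computes per-session Fisher-Z
    connectivity maps, between-session pattern similarity, temporal drift
    scores with parametric and permutation inference, a hippocampal
    longitudinal-axis gradient test, dependent-correlation comparisons
    between seed regions, confound-controlled pairwise regression, and
    network-restricted drift decomposition with false-discovery-rate
    control. Includes a multi-session phantom generator with known
    ground-truth drift rates and covariate couplings so that every stage
    of the pipeline can be validated against simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
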