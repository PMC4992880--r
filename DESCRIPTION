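Package: heatdecode
Title: Multi-Voxel Decoding of Heat Intensity from Simulated fMRI Block Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven pipeline for multi-voxel pattern analysis (MVPA)
    of thermode heat processing in blood-oxygen-level-dependent (BOLD) fMRI.
    Simulates factorial block-design experiments (heat temperature by emotional
    picture valence under a medication crossover) together with trial-level
    visual-analogue-scale rating tables; estimates per-condition beta maps with
    a first-level general linear model (boxcar regressors, canonical
    double-gamma haemodynamic response, discrete-cosine high-pass set, AR(1)
    prewhitening); trains a sparse voxel weight map for heat intensity by
    principal-component reduction followed by elastic-net regression with
    leave-one-subject-out cross-validation; applies the back-projected map to
    beta images via a by-voxel dot product to yield multi-voxel heat estimates
    (MHE); and evaluates decoding and behavioural effects with correlation,
    median-split classification, and factorial linear mixed models with Type
    III tests and estimated marginal means. Every stage runs on generated data,
    so the full chain is testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    glmnet,
    pbkrtest,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
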