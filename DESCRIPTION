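Package: gaitxai
Title: Multimodal Gait-Speed Classification with Layer-Wise Relevance
    Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying walking speed from multimodal gait
    recordings (3D marker trajectories, ground reaction forces, surface
    EMG, and foot forces and moments) and for explaining the resulting
    classifiers. Provides a synthetic gait-cohort simulator with subject
    random effects and known class-discriminative channels, multi-stream
    1-D convolutional networks and sequence-model baselines trained with
    Adam and early stopping, sample-wise and subject-wise cross-validation
    protocols, classification metrics with paired t-tests, layer-wise
    relevance propagation (epsilon, z, alpha-beta, flat and composite
    rules) together with gradient-family saliency baselines, a relevance
    aggregation protocol that maps channel relevance onto anatomical
    markers, and most-relevant-first (MoRF) region perturbation with
    area-over-the-perturbation-curve (AOPC) scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    e1071,
    data.table,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
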