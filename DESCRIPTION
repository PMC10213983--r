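Package: sleepExit
Title: Multi-Exit Adaptive-Depth Sleep Stage Classification from Multimodal
    Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sleep stage classification (AASM classes W, N1, N2, N3, REM) from
    30-second multimodal polysomnography epochs (EEG, EOG, EMG) with a
    multi-exit neural network that trades accuracy for computational cost at
    inference time. Each modality is encoded by a multi-scale one-dimensional
    convolutional feature extractor with channel and spatial attention; three
    classifier exits of increasing depth (EEG only, EEG+EOG, EEG+EOG+EMG)
    combine squeeze-and-excitation modality weighting with a transformer
    encoder. Training proceeds in two stages: the backbone and the final exit
    are trained with cross-entropy, then frozen while the two early exits are
    trained by self-distillation against the final exit. At inference a
    normalized-entropy gate routes easy epochs out of early exits under a
    single Speed threshold. Includes a seeded synthetic polysomnography
    generator with stage-specific spectral structure and modality-dependent
    difficulty tiers, EDF and hypnogram input handling with standard
    relabeling and wake-trimming rules, evaluation metrics, and closed-form
    FLOPs and parameter profiling with routing-weighted expected cost.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
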