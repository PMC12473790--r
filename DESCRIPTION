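Package: cate
Title: Cross-Corpus EEG Emotion Recognition with Dual-View Self-Supervised Pretraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CATE framework for cross-corpus electroencephalography
    (EEG) emotion recognition from differential-entropy band-power features.
    Stage one pretrains a shared two-layer feature extractor with a dual-view
    self-supervised objective: a noise-enhanced view (adaptive-scale Gaussian
    noise) and a wavelet view (level-1 Haar coefficient masking and perturbation
    of the five-band spectral profile), trained with a cosine alignment loss and
    a Gram-matrix style-diversity loss that prevents representation collapse.
    Stage two fine-tunes dual attention encoders initialised from the pretrained
    backbone, fuses them by averaging, and classifies with an MLP head under
    gradient clipping and a reduce-on-plateau learning-rate schedule. A synthetic
    two-corpus generator with controllable affine band shift makes the full
    transfer protocol runnable end to end without access to the SEED datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
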