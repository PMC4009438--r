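Package: hybridbci
Title: Hybrid NIRS-EEG Brain-Computer Interface Decoding Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and decoding for a hybrid near-infrared
    spectroscopy (NIRS) and electroencephalography (EEG) brain-computer
    interface. Builds block-design session schedules, simulates multimodal
    recordings with ground truth, converts raw two-wavelength optical
    intensities to oxy-/deoxy-hemoglobin concentration changes via the
    modified Beer-Lambert law, denoises hemodynamic traces (Gaussian low-pass
    and wavelet thresholding), extracts beta-band tapping features from motor
    channels C3/C4, classifies each modality with a from-scratch two-class
    linear discriminant, and fuses both streams into one of five control
    commands (Left, Right, Forward, Back, Stop).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
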