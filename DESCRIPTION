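Package: cufflessbp
Title: Cuffless Blood Pressure Estimation from ECG and PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end cuffless blood pressure estimation from synchronized
    single-lead ECG and fingertip photoplethysmography (PPG). Provides a
    synthetic waveform simulator with ground-truth fiducials and a known
    pressure-generating model, signal cleaning and fiducial detection
    (Pan-Tompkins QRS detection, wavelet-assisted PPG landmarking), beat-level
    morphological feature extraction, information-theoretic feature selection
    based on multivariate symmetric uncertainty (a fast-correlation filter
    hybridized with ReliefF), an elastic-net regression solver fit by cyclic
    coordinate descent, and evaluation against British Hypertension Society
    grading and AAMI-style error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
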