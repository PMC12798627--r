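Package: physiopipe
Title: Multimodal Psychophysiological Signal Cleaning, Feature Extraction and Nonparametric Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multimodal physiological session recordings
    (ECG, electrodermal activity, EMG, respiration): explicit signal-quality
    acceptability rules, notch/bandpass ECG cleaning with R-peak detection,
    EMG-guided motion-artifact repair of EDA with a 0-100 quality index,
    windowed-FFT respiration smoothing with mean-crossing breath-onset
    detection, heart rate variability LF/HF balance via Welch spectral
    estimation, and windowed feature assembly. Includes the matching
    statistical layer (Wilcoxon signed-rank and Mann-Whitney U tests with
    rank-biserial effect sizes, Benjamini-Hochberg and Holm corrections, and
    mixed repeated-measures ANOVA with Mauchly sphericity testing,
    Greenhouse-Geisser correction and generalized eta-squared), plus a
    seeded synthetic-session generator with known ground truth for
    end-to-end validation.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
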