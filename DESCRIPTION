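Package: neurostress
Title: Calibration-Free EEG Stress Neurometric with Physiological and
    Machine-Learning Comparators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a calibration-free electroencephalographic stress
    index (parietal high-beta band power anchored to the Individual Alpha
    Frequency) together with three comparator stress measures: mean skin
    conductance level from electrodermal activity, and random-forest
    classifiers trained intra-subject and cross-task on the same parietal
    features. Includes a synthetic generator of multichannel EEG, EDA and
    behavioral sessions emulating a multitasking battery and simulated
    driving runs, the full signal-processing pipelines (Butterworth
    filtering, blink correction, epoch-wise artifact rejection, alpha-peak
    estimation, band power, tonic/phasic EDA decomposition), ADASYN class
    balancing, and an evaluation framework with moving-average decimation,
    ROC AUC, curve correlation and distance, and nonparametric statistics
    (Friedman, Dunn, Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
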