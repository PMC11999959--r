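Package: mrcpspeller
Title: Movement-Related Cortical Potential Analysis for a Scanning Speller
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for movement-related cortical potentials
    (MRCPs) recorded during a scanning matrix-speller task. Simulates the
    column/row scanning paradigm, generates ground-truthed synthetic EEG and
    tibialis-anterior EMG with planted MRCP waveforms, and implements the full
    offline validation chain: Butterworth notch and band-pass filtering,
    epoching, demeaning, a large Laplacian spatial filter over Cz, EMG onset
    detection with morphological post-processing, peak-negativity
    identification, four per-trial acceptance criteria with success rates,
    MRCP feature extraction (PN, NS1, NS2, rebound, PP), and the statistical
    stage (Friedman omnibus, Wilcoxon signed-rank post-hocs with Bonferroni
    correction, grand averages, and one-dimensional statistical parametric
    mapping with cluster-level permutation inference).
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
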