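Package: phasecluster
Title: Phase-Synchrony Clustering and Time-Frequency-Topography Maps for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate assessment of phase synchrony in multichannel EEG.
    Extracts instantaneous phase with complex Morlet wavelets on a geometric
    frequency grid, clusters channels sample-by-sample by the magnitude of the
    circular mean resultant vector (fuzzy cluster growth reduced to disjoint
    hard partitions), encodes cluster membership as hexadecimal words, and
    renders Time-Frequency-Topography (TFT), intertrial TFT (iTFT) and
    Levenshtein-contrast (TFL) maps. Includes a synthetic EEG generator with
    an inverse-square-distance linear forward model, a chirped visual evoked
    potential, harmonic/white/colored noise sources with optional motion, and
    a P300-speller-like flash schedule, so the whole pipeline is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
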