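Package: iisr
Title: Integrated Information Structures from Multichannel Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computes integrated information structures (IIS) from
    multichannel neural recordings. Continuous voltage traces are bipolar
    re-referenced, segmented into epochs and binarized at the per-channel
    median; state-by-channel transition probability matrices are estimated
    at a configurable lag; and an exact engine for Integrated Information
    Theory (IIT 3.0) computes cause and effect repertoires, mechanism-level
    integrated information (phi) via minimum-information partitions,
    concepts, cause-effect structures and system-level integrated
    information (Phi) under unidirectional noising cuts, using the earth
    mover's distance with a Hamming ground metric. A coupled autoregressive
    surrogate-data generator, a study-level pipeline over channel subsets
    and nested cross-validated linear-SVM decoding of arousal state
    complete the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
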