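Package: abnremap
Title: Population-Level Remapping Analysis of Adult-Born Neuron Calcium Event Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistical pipeline for population-level analysis of sparse,
    deconvolved unitary calcium event trains from hippocampal adult-born
    neurons imaged across a contextual fear-conditioning paradigm. Provides
    temporal-aggregation statistics (circular autocorrelation, exponential
    decay fit, block-length estimation), moving-block-bootstrap classification
    of per-neuron responsiveness, cosine-similarity population-vector analysis
    with resampling-calibrated Ward clustering, a time-resolved remapping index
    over the memory-consolidation period with sleep/wake stratification, and a
    synthetic-experiment generator emulating the statistical structure of such
    recordings so every stage is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    minpack.lm,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
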