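Package: silicophys
Title: Neurophysiology-Style Analysis of Switch-Level Transistor Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A validation platform that treats a digital microprocessor-like
    circuit as a model organism for neuroscience methods. Provides a
    deterministic switch-level simulator for NMOS transistor netlists with
    per-transistor lesioning, and the standard systems-neuroscience analysis
    battery applied to the resulting activity: spike extraction and binning,
    stimulus tuning curves, spike-word population statistics with shuffle
    controls, spatially weighted local field potentials and Welch spectra,
    trial-based conditional Granger causality with BIC order selection,
    non-negative matrix factorization of population activity, and stochastic
    block model clustering of the transistor connectome. Ships synthetic
    ground-truth circuits and surrogate generators so every analysis can be
    scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
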