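Package: fcmodular
Title: Modular Functional Connectivity Networks and Metabolic Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds thresholded resting-state functional connectivity networks
    from regional time series, detects weighted modular partitions by greedy
    modularity maximization, computes intra- and inter-module connectivity under
    a reference partition, and relates module-level connectivity to single-voxel
    spectroscopy metabolite concentrations and clinical symptom scores. Includes
    motion and spectral-quality control filters (framewise displacement, Friston
    24-parameter nuisance regression, band-pass filtering, Cramer-Rao lower
    bound screening, cerebrospinal-fluid partial-volume correction) and a
    synthetic cohort generator with planted modular covariance structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
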