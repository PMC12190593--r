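Package: pacnet
Title: Phase-Amplitude Coupling, Band Power and Correlation Networks for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for working-memory EEG studies: delta-gamma
    phase-amplitude coupling quantified by the 18-bin Kullback-Leibler
    modulation index, Welch power spectral density with band-average
    log-power features, Pearson-correlation functional networks with node
    degree and clustering coefficients, and paired nonparametric
    comparisons. Includes a synthetic multichannel EEG generator with
    ground-truth cross-frequency coupling so every stage of the pipeline
    can be validated without access to clinical recordings.
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
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
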