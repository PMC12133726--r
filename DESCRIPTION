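Package: attnmi
Title: Attention-Modulated Lower-Limb Motor-Imagery EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for attention effects in lower-limb
    motor-imagery EEG. Provides a synthetic multichannel EEG generator
    with known attention-dependent spectral structure, EDF and plain-text
    I/O, resampling/band-pass/epoching/baseline preprocessing,
    wavelet-packet event-related spectral perturbation (ERSP) maps and
    event-related desynchronization (ERD) scalars, the alpha modulation
    index (AMI) and theta/beta ratio (TBR) attention indices in offline
    and simulated-online per-second modes, and the accompanying
    statistics: paired t-tests, Pearson correlations, Shapiro-Wilk
    checks, Bonferroni-corrected per-second tests, and cluster-based
    permutation tests in time-frequency and electrode space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
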