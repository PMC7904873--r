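Package: evokedstate
Title: State-Dependent Evoked Response Analysis for Cortical and Gut
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and comparison of stimulus-evoked activity across
    vigilance states in chronic electrophysiological recordings. Implements
    single-site evoked local field potential detection by the residual
    orthogonality test (pairwise trial product-sums compared to zero),
    Gaussian-kernel peristimulus spike-density estimation with a rule-based
    response criterion and five-way cell classification, multitaper (Slepian
    taper) band-power estimation for slow-wave-sleep staging and pre/post
    stimulus sleep-disturbance testing, and two-band analysis of duodenal
    myoelectric activity (sub-2 Hz slow waves and 3-10 Hz spike potentials).
    A seed-controlled synthetic-data generator emulates state-dependent EEG,
    evoked LFPs, inhomogeneous-Poisson spike trains and gut myoelectric
    signals so that every stage of the pipeline can be validated against
    ground truth.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
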