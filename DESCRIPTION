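Package: dgephys
Title: Dentate Gyrus Electrophysiology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable quantification chain for cellular and network
    electrophysiology of hippocampal dentate granule cells. Detects
    spontaneous and miniature postsynaptic currents in voltage-clamp sweeps
    and extracts their amplitude, frequency and kinetics; measures intrinsic
    excitability from current-step recordings (F-I curves, rheobase, action
    potential prominence and half-width, spike-frequency adaptation,
    depolarization block); quantifies evoked field potentials (fEPSP slope,
    population-spike amplitude, input-output curves, paired-pulse
    facilitation and inhibition, LTP time courses); fits Boltzmann sigmoids
    to EPSP-spike coupling and paired-pulse inhibition data with level
    interpolation and extra sum-of-squares curve comparison; and provides
    the accompanying statistics layer (D'Agostino-Pearson normality, Welch
    t with CI of the difference, exact Mann-Whitney with Hodges-Lehmann CI,
    chi-squared independence, repeated-measures ANOVA with a compound
    symmetry mixed-model variant, Bonferroni post-tests). A synthetic-data
    module generates sweeps and whole two-group studies with known ground
    truth, including an adaptive integrate-and-fire granule-cell simulator
    with depolarization block, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    signal,
    minpack.lm,
    pracma,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
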