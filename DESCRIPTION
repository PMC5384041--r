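Package: sleepspectr
Title: Sleep EEG Spectral Analysis and Architecture Metrics for Rodent Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for 48-h mouse EEG/EMG sleep studies:
    sleep-architecture metrics (state proportions, hourly profiles, episode
    statistics) from scored hypnograms; per-epoch FFT power spectra in 1-Hz
    bins (1-56 Hz) from bipolar-derived, filtered EEG; cohort-mean power
    normalization with iterative 300-percent artifact rejection; band-power
    time courses under two normalizations; and the matching statistical layer
    (pooled t-tests, split-plot repeated-measures ANOVA with Bonferroni
    post-hoc tests). Includes a seeded synthetic-polysomnography generator
    (Markov-chain hypnograms, state-dependent filtered-noise EEG, injected
    artifacts, EDF output) so the whole pipeline is testable without animal
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
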