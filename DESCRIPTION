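Package: hgconn
Title: Dynamic Task-Preferential High-Gamma Connectivity for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-related high-gamma (70-110 Hz) amplitude analysis for
    intracranial EEG and construction of time-resolved, streamline-gated maps of
    task-preferential functional connectivity. Implements complex-demodulation
    time-frequency estimation on a 10-ms by 5-Hz grid, percent-change
    normalization against a post-response baseline, per-bin permutation tests
    with Benjamini-Hochberg correction and a minimum-duration criterion,
    sliding-window linear mixed-model task contrasts with clinical covariates,
    tractography streamline filtering, and the simultaneity-plus-adjacency rule
    that turns region-level task effects into connectivity edges. A seeded
    synthetic cohort generator (pink-noise recordings with calibrated
    narrowband bursts, behavioral response times, subject covariates, and
    streamline sets) makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
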