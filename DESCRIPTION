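Package: hmmssf
Title: Population-Level Multi-State Step Selection Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits hidden-Markov multi-state step selection functions
    (HMM-SSF) to animal telemetry: state-specific discrete-choice
    (conditional multinomial) emission likelihoods, grouped forward
    likelihood for trajectories with gaps and irregular intervals,
    inverse-variance pooling of individual fits into population-level
    estimates, predictive state decoding, state-specific k-fold
    cross-validation, and analysis of behavioural transitions.  Includes
    two movement simulators with known true states (state-specific SSF
    walkers on patch landscapes, and a consumption-regeneration-memory
    biased correlated random walk on Gaussian random field landscapes)
    and a 2-step baseline estimator (gamma/von Mises hidden Markov
    movement model followed by per-state conditional logistic fits).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
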