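Package: ctxgate
Title: Context-Gated Suppression Analyses for Uncued Set-Shifting Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and analyses for audio-visual set-shifting experiments in
    which the relevant stimulus modality must be inferred from trial outcomes
    rather than signalled by a cue. Provides the task contingency model and
    the combinatorial five-trial sequence space, go/no-go behavioural
    analyses (moving-average consistency segmentation, Monte-Carlo
    consistency nulls, Bernoulli choice models with bias or lapse, d-prime),
    a synthetic population-recording generator with planted low-dimensional
    coding subspaces and tunable context-gated suppression, spike-train
    preprocessing to baseline-standardized instantaneous firing rates,
    time-resolved linear population decoding with decision-vector geometry
    (angles, subspace projections, chance calibration, block-averaged
    statistics), single-neuron modality and context indices, and a gateless
    recurrent network trained on five-trial sequences together with its
    weight-structure and representation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
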