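Package: mslrl
Title: Reinforcement-Learning Drift-Diffusion Modelling of Multisensory
    Statistical Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for model-based analysis of developmental multisensory
    association-learning experiments. Generates discriminative-choice and
    match-recognition task designs with manipulated pair/triplet presentation
    frequencies, probabilistic feedback reversal and gamma-distributed trial
    timing; computes trial-wise Shannon surprise from Laplace-smoothed
    combination frequencies; implements four Rescorla-Wagner learning variants
    coupled to a Wiener diffusion choice model with a first-passage-time
    likelihood; fits parameters per run by seeded multi-start maximum
    likelihood with BIC model selection; and provides forward simulation,
    parameter/model recovery harnesses, behavioural trial filtering and
    binning, reaction-time/surprise association summaries, and export of
    trial-wise parametric-modulator regressors for fMRI first-level models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
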