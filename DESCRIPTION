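Package: decidetime
Title: Meta-Bayesian Inference of Beliefs and Preferences from Reaction Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models trial-by-trial reaction times in probabilistic
    associative-learning tasks as the optimal decision times of a Bayesian
    observer facing a speed-accuracy trade-off. Provides a task simulator
    (blocked cue-outcome schedules, hidden association paths, noisy sensory
    signals), variational-Bayes recognition under static and dynamic (random
    walk) perceptual models, a closed-form optimal reaction-time response
    model, VB-Laplace inversion of the full response model from observed
    reaction times (posteriors over volatility and speed-accuracy
    parameters, free-energy bound on model evidence, reconstructed belief
    trajectories), random-effects group-level Bayesian model selection with
    exceedance probabilities, and a Monte-Carlo validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
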