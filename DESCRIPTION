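Package: fearscape
Title: Spatiotemporal Predator-Prey Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how large herbivores partition space and
    time in response to apex predators from camera-trap detection streams.
    Implements camera clustering and detection-independence filtering,
    circular kernel density estimates of diel activity with Ridout-Linkie
    overlap coefficients and bootstrap confidence intervals,
    time-stratified case-crossover conditional logistic regression of
    herbivore detections on recent predator presence, and hierarchical
    Bayesian Bernoulli detection models with effect-strength
    classification and posterior pruning. A synthetic detection-stream
    generator with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
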