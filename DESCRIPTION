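Package: attractorseq
Title: Sequence Discrimination in Point-Attractor Networks with Synaptic Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulations of randomly connected bistable excitatory
    units with a single shared inhibitory unit and short-term synaptic
    depression, together with the analysis pipeline for two sequence tasks: a
    six-item left/right evidence-accumulation task and a seven-item word-list
    task. Provides connectivity generation, stochastic Euler-Maruyama
    integration of the rate/gating/depression dynamics (compiled kernel),
    stimulus pattern and sequence generators (including balanced Latin-square
    designs), trial protocols with binarized state tables, L1 nearest-target
    decoding with confusion-matrix discrimination scores, perceptron readouts,
    psychometric and serial-position (primacy/recency) analyses, probability
    of first recall, parameter sweeps and ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
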