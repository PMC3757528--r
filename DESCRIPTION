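Package: skimnet
Title: Synthesis of Spiking Neural Networks for Spatio-Temporal Spike
    Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesizes two-layer spiking neural networks that recognize
    spatio-temporal spike patterns, using the synaptic kernel inverse
    method: input spike trains are projected through fixed random synaptic
    weights, filtered by per-dendrite synaptic kernels (alpha function,
    leaky integration, damped resonance, delayed alpha or Gaussian),
    compressed by a saturating nonlinearity, and the dendrite-to-soma
    weights are solved in a single pass by regularized linear least
    squares.  Includes batch and recursive (online) solvers, magnitude
    based synaptic pruning (two-pass and iterative), a generator for
    benchmark tasks (fixed spike patterns embedded in Poisson noise, with
    optional time warping and jitter), spike-detection scoring, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
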