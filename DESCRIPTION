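Package: scnet
Title: Spiking Neural Network Model of the Superior Colliculus Motor Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electrical microstimulation of the midbrain superior
    colliculus (SC) gaze-motor map with a two-dimensional network of adaptive
    exponential integrate-and-fire (AdEx) neurons coupled through Mexican-hat
    (difference-of-Gaussians) conductance-based lateral synapses on a log-polar
    topographic grid. An exponentially decaying electrode current field recruits
    a small set of neurons whose bursts spread through the lateral connections
    into a large, synchronized Gaussian population. Population spike trains are
    decoded into saccadic eye movements by dynamic linear ensemble coding, and
    the package quantifies burst properties (peak firing rate, burst duration,
    spike count, skewness, population synchrony) and saccade main-sequence
    kinematics (amplitude-duration and amplitude-peak-velocity relations),
    including phase-plane analysis utilities for the single AdEx neuron and
    scripted drivers for the standard microstimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
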