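Package: onsnn
Title: Online Neuroplasticity Spiking Neural Networks for Streaming
    EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an online neuroplasticity spiking neural network
    (O-NSNN): a three-layer leaky integrate-and-fire network that learns
    multichannel time-series classification on the fly under a
    test-then-train regime.  Continuous segments are converted to ternary
    spike trains by adaptive-threshold address event representation;
    input-to-hidden synapses adapt by spike-timing-dependent plasticity
    while hidden neurons regulate their own firing thresholds by intrinsic
    plasticity and self-prune on classification errors; the output layer
    evolves labelled rank-order neurons and eliminates persistently wrong
    ones.  Includes online and batch baselines without structural
    plasticity, prequential evaluation, a synthetic EEG-like stream
    generator with controllable input and concept drift, and
    model-interpretation reports (class-centroid distances, per-channel
    synaptic fan-out).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
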