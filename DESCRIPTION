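Package: evconvnet
Title: Event-Driven Convolutional Network Simulator with Rate Saturation
Version: 0.1.0
Authors@R:
    person("evconvnet", "developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Discrete-event simulator for modular event-driven convolutional
    neural networks operating on address-event representation (AER) spike
    streams, as produced by dynamic vision sensors. Implements a configurable
    integrate-and-fire convolutional unit with multi-kernel support, global
    leakage, and a hardware-faithful refractory (rate-saturation) mechanism
    based on an 8-bit time-slice register with overflow flag and periodic
    refresh; a destination-driven 2D mesh router; a network assembler with
    FIFO backpressure and input event dropping (traffic control); a two-stage
    frame-to-event parameter mapping with an optional simulated-annealing
    tuner; synthetic stimulus generators (ISI-controlled spike trains and
    moving-symbol DVS emulation); and analysis utilities for saturation
    curves, classification decisions, stream statistics and energy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
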