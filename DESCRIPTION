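Package: memsctrnn
Title: MEMS-Based Continuous-Time Recurrent Neural Networks for
    Wearable Activity Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates networks of electrostatically actuated MEMS
    devices operating in the pull-in/release regime as neurons of a
    continuous-time recurrent neural network (CTRNN), and trains them by
    backpropagation through time with a surrogate gradient for binary
    human-activity detection on windowed accelerometer time series.
    Includes ternary signal quantization, mutation-based training-set
    augmentation, a reference software CTRNN baseline, a seeded synthetic
    recording generator emulating 50 Hz tri-axial signals, evaluation
    protocols (70/30 splits, hidden-size and time-constant sweeps,
    labeling-threshold and input-channel ablations), readers and writers
    for raw recordings and window datasets, and a capacitor-switching
    power model for the physical network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
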