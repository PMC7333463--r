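Package: calciflow
Title: Dataflow-Based Real-Time Neuron Detection and Calcium Signal
    Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dataflow-structured pipeline for real-time analysis of
    miniature two-photon calcium imaging video: adaptive rigid motion
    correction built on the enhanced correlation coefficient criterion,
    multi-threshold blob-based neuron detection with a training mode and
    progressive parameter loosening, per-neuron relative-fluorescence
    (delta-F/F) trace extraction, a ground-truthed leaky
    integrate-and-fire calcium-imaging simulator, and a quantitative
    evaluation harness for motion, detection and signal-to-noise
    accuracy. The processing graph is expressed in a small parameterized
    synchronous dataflow runtime with actors, FIFO edges and dynamic
    parameter rebinding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
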