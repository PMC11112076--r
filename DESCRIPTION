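Package: tmseegsim
Title: Simulation-Based Benchmarking of TMS-EEG Muscle-Artifact Rejection
Version: 0.1.0
Authors@R:
    person("TMS-EEG simulation contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Generates synthetic ground-truth TMS-evoked EEG potentials,
    superposes parametrically controlled scalp-muscle artifacts built from
    Daubechies wavelet time courses and spherical head-model topographies,
    cleans the corrupted data with both SSP-SIR (signal-space projection with
    source-informed reconstruction) and FastICA component subtraction, and
    quantifies recovery of the ground truth across a grid of artifact
    topographies and inter-trial variabilities.  Also provides the artifact
    characterization operators used on measured data: SVD artifact
    extraction, inter-trial coherence, minimum-norm montage extrapolation,
    and signal-space angle distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
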