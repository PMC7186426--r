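Package: dfhm
Title: Dual Frequency Head Maps Workload Index from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an EEG-based mental-workload monitoring pipeline built
    on Dual Frequency Head Maps (DFHM): bandpass filtering, Infomax ICA
    artifact rejection, Hjorth-style surface Laplacian, segmentation, FFT band
    power in the theta (4-8 Hz) and alpha (8-12 Hz) bands, personalized
    z-scoring against a first-minute baseline, support-vector-machine
    classification into three workload classes, and a 30-second moving-average
    workload index on a 0-100 scale.  Also provides the surrounding validation
    toolkit for air-traffic-control simulation studies: an
    instantaneous-self-assessment (ISA) workload-sensitivity index with
    median-split clustering, trajectory-based performance metrics (route
    distance, wake-vortex loss-of-separation detection, paired Wilcoxon
    signed-rank tests), repeated-measures and mixed ANOVA with
    Greenhouse-Geisser correction, and a synthetic-data generator producing
    EEG, ISA ratings and arrival trajectories with the statistical structure
    the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
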