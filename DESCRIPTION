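Package: steerscope
Title: Kinematic and Neural Analysis of Steering and Exploratory Turns in
    Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline separating rapid steering turns from slow
    exploratory turns in larval-zebrafish tail kinematics and relating turn
    amplitude to neural recruitment. Segments tail-angle traces into
    fixed-window locomotor bouts, classifies bouts by dynamic-time-warping
    time-series k-means followed by a cubic (Minkowski p = 3) k-nearest-
    neighbour classifier on kinematic features, computes calcium dF/F
    responsiveness and recruitment summaries for ROI fluorescence traces,
    and analyses intracellular recordings (dV/dt spike detection,
    recruitment-angle estimation, spike-count regressions, postsynaptic-
    potential amplitude and synaptic-delay measurement, gap-junction
    coupling coefficients). A seeded synthetic-data generator with
    documented ground truth emulates the kinematics, spiking, calcium and
    paired-recording data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
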