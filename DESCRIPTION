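Package: fqrs
Title: Automated Detection and Quantification of Fragmented QRS in Multi-Lead ECG
Version: 0.1.0
Authors@R:
    person("fqrs", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Fully automated per-lead scoring of QRS fragmentation (fQRS) in short
    resting 12-lead electrocardiograms. Implements robust multi-lead QRS
    segmentation (per-lead R-peak detection with cross-lead consolidation,
    wavelet-based QRS delineation with median reallocation, template alignment
    and a correlation quality filter), per-lead feature extraction based on
    variational mode decomposition, phase-rectified signal averaging and QRS
    peak counting, a support-vector-machine classifier with Platt-calibrated
    continuous scores in [0, 1], evaluation metrics (sensitivity, specificity,
    PPV, ROC/PR AUC, Cohen's kappa threshold sweep, ordinal-label correlation),
    and a synthetic multi-lead ECG generator with full ground truth for testing
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
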