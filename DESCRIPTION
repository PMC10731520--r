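Package: duobrain
Title: Dual-Mouse Mesoscale Calcium Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of simultaneous widefield ("mesoscale")
    GCaMP calcium imaging from two interacting head-fixed mice. Converts
    dual-channel (fluorescence + reflectance) image stacks to
    hemodynamics-corrected fractional-change (dF/F0) stacks, extracts binary
    whisker/forelimb behavior events from video ROI motion energy, aligns
    cortical windows to atlas coordinates via anatomical key-points, computes
    interbrain correlation and multitaper coherence statistics with
    trial-shuffle nulls, and fits a ridge-regression encoding model with
    cross-validated explained-variance and unique-contribution (delta R
    squared) maps. Includes a synthetic paired-session generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
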