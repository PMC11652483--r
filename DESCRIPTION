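Package: epidlog
Title: Control-Point Specific VMAT QA from Sequential EPID Images
Version: 0.1.0
Authors@R:
    person("EPID", "QA Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts time-ordered electronic portal imaging device (EPID)
    frames acquired during volumetric modulated arc therapy (VMAT) delivery
    into a machine-log style record of per-frame multi-leaf collimator (MLC)
    positions and monitor units (MU). Implements raw-image inversion,
    additive iterative deconvolution with a Gaussian scatter kernel,
    calibrated threshold binarization, per-leaf edge extraction with
    gantry-sag and collimator-shift offset correction, pixel-scaling-factor
    MU conversion, and an open text log dialect. Also provides the standard
    VMAT plan-complexity indices (MCSv, AAV, LSV, LT, SAS, LTMCS), control
    point transition metrics, a 2D gamma comparator, Spearman rank
    correlation analysis of gamma passing rates, and a fully synthetic
    acquisition generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
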