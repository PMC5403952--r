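Package: cyclogait
Title: Cyclogram-Based Gait Disparity Analysis and Dominant Parameter
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds coupled kinematic/kinetic cyclograms from
    stride-normalized lower-limb gait trials, quantifies per-sub-phase
    disparity of pathological gait against a trial-averaged normal
    reference using small linear feed-forward networks and a curve
    closeness statistic, and runs a normal-value substitution procedure
    that identifies the dominant joint parameter in each gait sub-phase,
    including a knee-only restriction for powered prosthetic knee design.
    Includes a synthetic gait generator for normal, transtibial,
    transfemoral and orthosis cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
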