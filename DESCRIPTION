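Package: saltatrack
Title: Trajectory, Directionality and Morphology Analytics for Saltatory
    Neuronal Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the tangential migration of midbrain dopaminergic
    neurons from 3D time-lapse cell tracks: per-frame soma kinematics,
    max-speed migration classes, speed-band phase occupancy, displacement
    and directionality, midline-referenced trajectory angles with circular
    summaries and a two-sample Kuiper test, morphology-state and branch
    dynamics, and mediolateral distribution analytics for fixed sections.
    Includes a hidden-state generative model of saltatory migration
    (rest-dominated movement with rare, laterally biased fast spurts and
    speed-coupled bipolar/multipolar morphology) for validation and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
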