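Package: ploidyscope
Title: Fluorescence-Based DNA Content and Nuclear Architecture Across a
    Foraminiferal Life Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies nuclear DNA content from Hoechst-stained confocal
    z-stacks across the life cycle of the foraminifer Allogromia
    laticollaris strain CSH. Provides 3D nuclear segmentation with
    volume and integrated-fluorescence measurement, calibration of
    fluorescence to base pairs against standards of known genome size
    (two estimators and their dispersion comparison), C-value
    normalization against the gamete median, radial-profile
    classification of nuclear architecture (homogeneous, DNA-poor
    center, vegetative ring), skeleton-based morphometry of Zerfall
    chromatin threads and puncta, and stage-duration, emergence-class,
    transition and synchrony statistics from longitudinal observation
    tables. A synthetic confocal scene generator with full ground truth
    makes every stage of the pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
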