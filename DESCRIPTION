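Package: polarleaf
Title: Stokes Polarimetric Imaging Analysis for Plant Stress Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rotating-quarter-wave-plate Stokes polarimetry of plant
    leaves. Reconstructs per-pixel Stokes parameter images from modulated
    intensity stacks by harmonic least squares, filters pixels by degree of
    polarization, characterises the circular polarization component |s3| with
    generalized extreme value (GEV) statistics, and relates GEV parameters to
    growth time and salt-stress level via rank tests, ANOVA and linear
    regression. Includes a Mueller-optics simulator of virtual leaves (per-pixel
    retarder/diattenuator/depolarizer fields) for end-to-end validation, and a
    Lu-Chipman polar decomposition of measured Mueller matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
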