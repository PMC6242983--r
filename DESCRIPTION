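Package: mpmwound
Title: Label-Free Multiphoton Imaging Analysis of Wound-Edge Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal label-free multiphoton
    microscopy of skin wound healing: motion-artifact rejection and
    registration of repeated in vivo z-stacks, fluorescein/PMT power-law
    intensity calibration, per-pixel optical redox ratio FAD/(NADH+FAD)
    mapping of the epithelial wound edge, incomplete bi-exponential fitting
    of NADH TCSPC fluorescence-lifetime decays with phasor analysis,
    Ki67/DAPI proliferation indexing, and nested mixed-effects statistics
    for repeated in vivo measurements. Includes a synthetic-acquisition
    generator with known ground truth that emulates the full experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    tiff
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
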