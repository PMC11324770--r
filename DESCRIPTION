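Package: tjscreen
Title: Tight-Junction High-Content Screening with Synthetic Imaging and Lung PBPK
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for an occludin-based epithelial
    barrier-integrity imaging assay. Generates synthetic three-channel
    (nuclei / whole-cell / junction) monolayer fields and full screening plates
    with ground truth; quantifies membrane and junction staining by
    nuclei-seeded segmentation of the inverted cell-mask channel, a 1-pixel
    membrane outline grown into a +/-10 pixel band, and overlap with a
    thickened junction mask; fits dose-response curves with an IC50
    establishment rule and Cooper predictivity statistics; and simulates
    generation-resolved lung disposition of inhaled compounds (Nernst-Brunner
    particle dissolution, mucociliary clearance, permeability-limited
    epithelial uptake, perfusion-limited systemic exchange) to map epithelial
    lining fluid exposure onto the in vitro dose-response curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
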