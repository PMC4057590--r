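Package: mbceus
Title: Quantification of VEGFR2-Targeted Contrast-Enhanced Ultrasound,
    Strain Elastography and Xenograft Growth Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for ultrasound-based monitoring of antiangiogenic
    therapy in small-animal tumour models. Implements
    destruction-replenishment quantification of targeted microbubble
    contrast (differential targeted enhancement, dTE) from cine loops,
    including inversion of the scanner's logarithmic display compression,
    peak-enhancement scoring of non-perfused tumour area on a 10% step
    scale with two-reader consensus, tumour-to-pad strain-ratio
    elastography, and tumour-volume/response arithmetic with the
    tie-corrected nonparametric group statistics customary in such
    studies. A synthetic cine, strain-image and cohort generator with the
    kinetic and statistical structure the analysis assumes makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
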