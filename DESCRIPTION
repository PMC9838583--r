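Package: uwfvasc
Title: Ultra-Widefield Retinal Vascular Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies retinal vascular morphology on ultra-widefield
    scanning-laser ophthalmoscope images: branching complexity as the
    multifractal sandbox dimension D0 of the vessel skeleton inside
    standardized regions of interest, vessel width gradient (robust
    regression slope of width against arclength, um/mm), and a unitless
    curvature tortuosity, each per retinal quadrant and vessel class.
    Group differences between cohorts (e.g. Alzheimer's dementia, mild
    cognitive impairment, normal cognition) are tested with linear-link
    generalized estimating equations that cluster the two eyes of a
    participant under an exchangeable working correlation. A synthetic
    vascular-tree generator with known ground truth (branching density,
    width taper, sinuosity, arteriole/venule labels, eyelash and eyelid
    artifacts) supports validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
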