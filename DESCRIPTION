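Package: crmbiofilm
Title: Tag-Free Confocal Reflection Microscopy Analysis of Biofilm
    Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of biofilm microcolony structure from
    confocal reflection microscopy (CRM) z-stacks acquired over
    index-matching material (IMM) coated substrates. Provides closed-form
    confocal/IMM optics (axial resolution, Airy unit, Fresnel
    reflectance, effective numerical aperture, minimum layer thickness),
    interface localization and background quantification, 3D single-cell
    segmentation, per-cell pitching-angle morphometrics from second
    moments, cell-density profiling and heatmaps, and a synthetic
    reflection z-stack simulator (spherocylinder cells under layered or
    isotropic orientation models, interface reflection, PSF blur, noise,
    saturation) used as ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
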