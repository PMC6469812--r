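Package: cortimetry
Title: Cortical Bone Cross-Section Morphometry and Strength Association
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the pore microstructure of cortical bone from
    calibrated 2D cross-section images (acoustic impedance maps or CT
    density slices). Provides segmentation of the cortical compartment
    from a manually delineated endosteal boundary, per-pore
    largest-inscribed-circle diameters via the Euclidean distance
    transform, modal cortical thickness, and the full set of
    threshold-stratified porosity parameters (Ct.Po, Po.D, relPo.n,
    relCt.Po at 60-385 um pore-diameter cutoffs). A statistics layer
    computes Pearson correlations with Fisher confidence intervals,
    partial correlations controlling for areal bone mineral density,
    and multivariate linear models with standardized coefficients. A
    seeded synthetic cross-section and cohort generator with exact
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics
RoxygenNote: 7.3.3
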