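Package: boneCSG
Title: Cross-Sectional Geometry and Cortical Porosity of Growing Long Bones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies diaphyseal cross-sectional geometry and intracortical
    porosity of epiphysis-free long bones from micro-CT style voxel volumes.
    Volumes are binarized with a minimum (histogram-valley) threshold, aligned
    to their principal axes, and sliced at fractional positions of
    intermetaphyseal length; each section yields total, cortical and medullary
    areas, second moments of area about anatomical and principal axes,
    cortical porosity area, and the derived medullary (MA/TA) and porosity
    (CPA/CA) indices. Cohort-level tools bin individuals into locomotor
    stages, fit LOESS ontogenetic trend curves, summarise stages with Tukey
    box-plot statistics, and estimate age from femur length via an invertible
    cubic growth curve. A synthetic phantom generator provides tapered
    elliptical-annulus volumes with planted pores and exact closed-form ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
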