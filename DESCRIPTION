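Package: eamrisk
Title: Spherical Normalization of Electroanatomic Maps and Arrhythmic Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms left-ventricular electroanatomic-mapping point exports
    (position, unipolar/bipolar voltage, local activation time, impedance) into
    spatially normalized substrate features by projecting each point cloud from
    its centroid onto a fixed sphere tessellated into 14,400 equal-area faces
    partitioned into 8 anatomically labelled regions. Derives activation-gradient
    (GR), voltage-discrepancy (VLT), late-potential extent (LAT), scar-area and
    regional-impedance features, screens and assembles clinical covariate tables,
    and fits and searches predictive models for major arrhythmic events
    (logistic regression, linear and RBF-kernel support vector machines, small
    neural networks) with cross-validated evaluation and Shapley-value
    attribution. Includes a synthetic cohort generator with planted substrate
    abnormalities so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
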