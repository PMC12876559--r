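Package: stenoshape
Title: Geometry-Aware Data-Driven Lumped Arterial Stenosis Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for building a geometry-aware lumped (0D)
    arterial stenosis model: generation of synthetic axisymmetric stenotic
    vessel cohorts by quasi-Monte-Carlo severity sampling, statistical shape
    modeling by principal component analysis of template-to-target
    displacement fields, a desk-scale flow oracle producing reference
    pressure-drop data across Reynolds numbers, two-regime least-squares
    estimation of viscous and expansion loss coefficients, Gaussian-process
    regression of loss coefficients on shape coefficients with composite
    kernels and cross-validated hyperparameter search, and fractional flow
    reserve prediction with agreement and classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
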