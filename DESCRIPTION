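Package: cortdev
Title: Developmental Trajectories of Cortical Thickness with IQ Moderation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether case-control differences in brain
    anatomy vary with IQ in developmental cohorts. Implements vertexwise
    semiparametric age-trajectory modelling of cortical thickness with a
    locally-weighted running-line smoother, parsimony-based selection of
    effective degrees of freedom along a nested ladder, pooled-versus-
    separate trajectory difference tests with Benjamini-Hochberg false
    discovery rate control across the cortical surface, covariate-adjusted
    volumetric general linear models with IQ-by-diagnosis moderation and
    median-split subgroup analyses, and a calibrated synthetic-cohort
    generator (phenotypes, volumetric measures, and spatially smoothed
    thickness maps on a toy triangulated surface) so the full analysis can
    be exercised and validated without access to any original MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    igraph,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
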