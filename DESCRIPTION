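Package: maxentSDM
Title: Maximum-Entropy Habitat Suitability Modelling for Translocation-Site Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A presence-background species distribution modelling pipeline for
    screening candidate translocation sites. Implements hinge-feature
    maximum-entropy models with L1 regularization fitted by cyclic coordinate
    descent, terrain predictors (roughness, north-facing aspect fraction,
    vegetation class fractions) derived from elevation and vegetation rasters,
    repeated k-fold cross-validation with AUC/TSS evaluation, AUC-weighted
    ensembling, permutation variable importance, limiting-factor maps, and a
    spatial null-group test that compares hold-out site suitability against
    random groups of background cells. Includes a synthetic-landscape generator
    (autocorrelated elevation, correlated climate fields, categorical
    vegetation mosaics and virtual-species occurrences) so the whole workflow
    is testable end to end with known ground truth, plus single-band GeoTIFF
    raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Rcpp, jsonlite, yaml, sp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'raster-core.R'
    'geotiff-io.R'
    'synthetic-landscape.R'
    'predictor-engineering.R'
    'occurrence-prep.R'
    'maxent-features.R'
    'maxent-fit.R'
    'maxent-interpret.R'
    'evaluation-ensemble.R'
    'spatial-validation.R'
    'pipeline.R'
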