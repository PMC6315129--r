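Package: facesym
Title: Dense Facial Asymmetry Phenotyping and Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies bilateral facial asymmetry from 3D triangulated
    surface meshes. Builds dense point correspondence between a base mesh
    and each subject via landmark-guided thin-plate-spline warping and
    closest-point projection, mirrors each face across the midsagittal
    plane, and derives per-point asymmetry features (angle of surface
    orientation, angle of deformation, deformation magnitude). Subjects
    are scored against a population model of normal asymmetry with a
    spatially augmented histogram distance whose bins carry coherent
    mesh regions. Includes landmark- and magnitude-based baseline
    phenotypes, a quantitative-trait association stage (minor-allele
    carrier filtering, genotype principal components, linear models with
    age and sex covariates, Benjamini-Hochberg correction), and a
    synthetic cohort generator with controlled asymmetry injection and a
    planted causal variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
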