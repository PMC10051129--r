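Package: tvsim
Title: Tricuspid Valve Closure Simulation and Regurgitation Severity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying tricuspid regurgitation in hypoplastic left
    heart syndrome with synthetic valve cohorts. Generates parametric
    pseudo-populations of tricuspid valve geometries (annulus diameters,
    bending angle, leaflet heights, systolic annular area change), simulates
    quasi-static valve closure with a mass-spring membrane model under
    transvalvular pressure with chordae tethering and leaflet contact, scores
    regurgitation severity as the maximum regurgitant orifice area over a
    top-down and eight offset projection viewpoints, grades severity by
    k-means clustering of log orifice area, identifies multivariate
    predictors by LASSO-penalized logistic regression with ROC and
    precision-recall evaluation, and estimates tissue stiffness parameters by
    inverse simulation against segmented point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
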