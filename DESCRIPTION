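Package: ceratomorph
Title: Landmark-Based Geometric Morphometrics of Ceratomyxid Myxospores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the landmark-based geometric-morphometric analysis of
    crescent-shaped (ceratomyxid) myxozoan spores seen in sutural view: an
    eight-landmark construction on spore outlines, traditional measurements
    (length, thickness, posterior angle), generalized Procrustes analysis,
    object-symmetry decomposition into symmetric and asymmetric shape
    components, digitization quality control (repeatability, percent
    measurement error, outlier screening), morphospace analysis (PCA,
    eigenvalue-ratio retention rule, landmark contributions, thin-plate-spline
    deformation grids, convex hulls), and Procrustes ANOVA/ANCOVA with
    residual-randomization permutation (RRPP) inference, including a
    permutational test of multivariate dispersion. A parametric crescent-spore
    simulator generates outline and landmark datasets with host structure,
    allometry, bilateral asymmetry and digitization noise, calibrated so that
    its default population reproduces the summary statistics of a published
    five-host Ceratomyxa dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
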