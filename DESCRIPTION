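Package: lensmetry
Title: Ex Vivo MRI Biometry of the Crystalline Lens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring the crystalline lens in three-dimensional
    volumetric MRI of fixed eyes. Implements the full measurement chain:
    volume I/O (NIfTI-1 and Analyze 7.5), per-eye cropping from multi-eye
    array scans, Gaussian pre-smoothing, threshold flood-fill segmentation
    with automated slice-wise hole repair, shrink-wrap fitting of a closed
    triangular mesh with fixed face budget, and mesh-based biometry (axial
    thickness, equatorial diameter, volume, anterior and posterior radii of
    curvature via an axis-constrained Powell sphere fit, and an objective
    classifier for the fixation-induced "kidney" anterior-surface
    depression). A companion phantom module generates ground-truthed
    biconvex eye phantoms, 2x2x4 eye arrays with Rician noise, and
    correlated synthetic bird cohorts with a hatch-level shrinkage artifact,
    so that every pipeline stage can be validated against known truth.
    A statistics layer provides the trait-analysis toolkit: Spearman rank
    correlations, Lilliefors normality screening, paired t comparisons,
    repeat-scan repeatability tables, trait correlation maps, and logistic
    likelihood-ratio tests of batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    Matrix,
    MASS,
    nortest,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
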