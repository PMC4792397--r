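Package: rehomvpa
Title: Regional Homogeneity MVPA for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end multivariate pattern analysis pipeline for
    resting-state fMRI based on regional homogeneity (ReHo). Computes
    voxelwise Kendall's coefficient of concordance maps over 7/19/27-voxel
    neighborhoods, normalizes and smooths them, ranks voxel features with
    the ReliefF algorithm, classifies subjects with a nested leave-one-out
    linear support-vector machine over an incremental feature-count grid,
    and assesses significance with label-permutation tests and Monte-Carlo
    cluster-extent-corrected voxelwise correlation maps. A seeded synthetic
    cohort generator produces 4D volumes with implanted synchrony clusters
    and matched clinical covariates so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Matrix,
    e1071,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
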