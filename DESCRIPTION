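Package: voxrfe
Title: Spatially Constrained SVM Recursive Feature Elimination for 3D
    Brain Volumes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classification of two-group cohorts of co-registered 3D
    functional brain volumes (e.g. perfusion SPECT or PET maps) at the
    voxel level. Implements information-gain voxel screening with
    MDL-stopped supervised discretization, density-based spatial
    clustering of voxels on the integer lattice (18-connectivity
    DBSCAN), Monte-Carlo cluster-extent thresholding, iterative linear
    SVM-weight feature elimination constrained to spatially connected
    clusters, grid-searched SVM model selection, and stratified k-fold /
    leave-one-out evaluation. A synthetic cohort generator with planted
    discriminative clusters makes every stage testable without clinical
    data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    e1071,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
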