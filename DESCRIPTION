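Package: memflat
Title: Membrane Flattening and Particle Geometry for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms a curved membrane and its neighborhood inside a
    cryo-electron tomogram into a flattened tomogram whose z-axis is
    perpendicular to the membrane everywhere. Provides seeded surface
    extraction from membrane masks, polynomial and thin-plate-spline
    height-surface fitting, cylindrical unrolling with equal arc-length
    sampling, trilinear rendering of the flattened volume, per-pixel
    distortion maps from the first fundamental form, bidirectional
    coordinate mapping, a UV-parameterized mesh pathway, and a particle
    layer (duplicate removal, normal-direction projections, missing-wedge
    2D weighting, Euler-angle construction) that turns flattened-space
    picks into subtomogram-averaging-ready metadata. A phantom generator
    produces synthetic tomograms, masks, meshes, and ground-truth tables
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
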