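Package: chullmass
Title: Convex-Hull Volumetric Body-Mass Estimation from Articulated Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates body mass of extinct vertebrates from 3D skeletal
    geometry using the minimum convex hull technique. Computes per-segment
    convex hull volumes of articulated skeletons from OBJ/PLY/STL meshes or
    point clouds, calibrates log-log mass-volume regressions on extant
    specimens by ordinary least squares and phylogenetic generalized least
    squares under Brownian motion, and predicts fossil body mass with 95%
    prediction intervals, smearing back-transformation correction,
    density-based hard lower bounds and viscera correction. Ships an extant
    pigeon calibration table and dodo skeleton hull volumes as fixtures,
    together with synthetic-data generators with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
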