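Package: ventriwall
Title: Finite-Element Analysis of Lateral Ventricular Wall Loading and
    Periventricular White Matter Hyperintensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static hyperelastic finite-element simulation of
    hemodynamic pressurization of an idealized brain domain, with the
    mechanomarkers used to rationalize periventricular white matter
    hyperintensity (pvWMH) locations on the lateral ventricular wall.
    Provides a seeded synthetic phantom generator (ellipsoidal ventricle
    with high-curvature horns inside layered white matter, gray matter
    and subarachnoid shells, plus FLAIR-like intensity volumes), a
    one-term Ogden material with volumetric/isochoric split, a nonlinear
    tetrahedral solver with follower pressure loads, Laplace-field wall
    frames, projection stretches and the ependymal thinning ratio, mean
    wall curvature by bi-quadratic patch fitting, normal-ray pvWMH
    thickness, intensity-threshold WMH segmentation with CSF-adjacent
    component removal, and the pooled two-sample comparison of markers
    in WMH versus adjacent wall regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
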