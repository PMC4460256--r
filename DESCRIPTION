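Package: acuhead
Title: Localization of Standardized Acupuncture Points on 3D Head Surface Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for localizing the 65 standardized head acupuncture points on
    three-dimensional surface models reconstructed from axial image stacks.
    Provides a synthetic two-shell head phantom generator with analytically
    known ground-truth landmarks, voxel preprocessing (thresholding, hole
    filling, boundary extraction), isosurface triangulation with vertex-normal
    averaging, anatomical reference frames and planes, an encoded catalog of
    the head acupoint taxonomy (anatomical, proportional, morphological), an
    angle-ratio solver for proportional points, and a control-point
    distance-minimization solver for morphological points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
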