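Package: meshcarto
Title: Crystal Cartography for X-Ray Diffraction Mesh Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-dimensional X-ray diffraction mesh (raster) scans
    in macromolecular crystallography. Detects grid nodes whose still images
    superpose several crystal lattices using difference-diffraction-vector
    (DDV) statistics, groups the remaining nodes into individual crystals by
    hierarchical clustering of an angular spot-similarity score, and fits each
    crystal's footprint and diffraction strength with a semi-ellipsoid,
    producing a ranked crystal list and a crystal map. Includes a synthetic
    mesh-scan simulator based on the Ewald construction for still images,
    which provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
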