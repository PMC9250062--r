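Package: fontangraft
Title: Parametric Fontan Graft Design and Hemodynamic Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless construction of tube-shaped and bifurcated Fontan
    (total cavopulmonary connection) vascular grafts as watertight triangle
    meshes from cubic Bezier centerlines and elliptical anastomosis
    cross-sections, and evaluation of their hemodynamic performance against
    clinical benchmark ranges: indexed power loss from boundary energy
    fluxes, the nonphysiologic wall-shear-stress fraction below 1 dyne/cm2,
    and hepatic flow distribution by Lagrangian particle tracking. Includes
    OBJ/STL mesh exchange, a design-sketch CSV format for saving and
    rebuilding grafts, an HDF5-to-CSV converter for simulation result
    bundles, analytic flow fixtures with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
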