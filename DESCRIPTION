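Package: vortexstab
Title: Vortex-Core Identification and Temporal Stability Analysis for
    Intra-Aneurysmal Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies vortex-core regions in time-resolved 3D velocity
    fields on rectilinear grids using the Q-criterion and lambda2 methods
    (plus velocity-normalized variants), segments them by threshold-ladder
    binarization, connected-component labeling and a minimum-volume filter,
    and quantifies temporal flow stability over the cardiac cycle via the
    Degree of Vortex Overlap (DVO) against a cycle-averaged structure and
    via vortex-core-count variation. Includes hemodynamic wall metrics
    (time-averaged wall shear stress, oscillatory shear index), geometric
    characteristics of an aneurysm sac mesh, agreement and correlation
    statistics, and an analytic synthetic-flow generator (solid-body,
    Lamb-Oseen, shear) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xml2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
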