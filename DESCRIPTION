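Package: fragarch
Title: Tree Architecture, Allometry and Biomass Under Forest Edge Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing edge effects on tree architecture and
    allometry in fragmented tropical forests. Computes architectural traits
    (path fraction, crown asymmetry, surface area per unit volume, relative
    crown dimensions) from cylinder-based quantitative structure models
    (QSMs) of single trees, fits allometric models for woody volume with
    nested random intercepts, scans for the spatial extent of edge effects
    along a distance-to-edge gradient, and decomposes plot-level
    aboveground-biomass differences between edge and interior forests into
    structure and allometry components. Includes a synthetic stand and
    census generator with recorded ground truth for parameter-recovery
    simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
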