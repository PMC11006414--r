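Package: nestflux
Title: Curvature, Evaporation Flux and Collective Construction on Voxelized Nest Topographies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how substrate geometry organizes collective
    building on humid substrates, motivated by early nest construction in
    termites. Provides parametric arena scenes and their voxelization (with a
    reader for surface-scan meshes), a curvature-driven phase-field growth
    simulator with a frozen-substrate rule, a steady-state diffusive humidity
    (Laplace) solver yielding gradient and surface evaporation-flux maps, a
    timelapse image-analysis pipeline turning building videos and trajectory
    tables into collection/deposition/occupancy probability maps and radial
    profiles, and a seeded synthetic timelapse generator with a ground-truth
    event log so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
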