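Package: pathcv
Title: Path Collective Variables, Umbrella Sampling and WHAM on Model Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for free-energy simulation strategies built on
    path collective variables. Provides frames and optimal superposition, the
    progress (S) and distance (Z) path variables with analytic gradients, a
    seedable Langevin engine over pluggable analytic potentials and charged
    clusters, steered pulling with work accounting, iterative reaction-path
    refinement, umbrella-sampling campaigns, weighted-histogram (WHAM)
    reconstruction of 1D profiles and 2D surfaces with block-bootstrap errors,
    and downstream analyses: minimax minimum free energy paths, projections,
    observables binned along the path, steered-work barrier estimates,
    gradient-projection diagnostics and zero-point-charge mutant comparisons.
    All test systems are generated analytically with oracle-verifiable free
    energies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
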