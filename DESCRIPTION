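Package: wconn
Title: Weighted Connectome Construction, Metrics and Small-World Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses dense weighted structural brain networks
    (connectomes). Provides a dimensionless, scale-invariant edge weight
    computed from streamline geometry (streamline counts and lengths, seed
    density, voxel volume and node surface areas), streamline-count
    thresholding, binary and weighted network metrics (degree, strength,
    min-hop/max-weight geodesic path lengths, binary, Onnela and
    Zhang-Horvath clustering coefficients), dual-constrained null models
    preserving the degree sequence and the edge-weight multiset, and the
    small-worldness statistic (gamma, lambda, sw) for binary and weighted
    frameworks. Includes synthetic-connectome generators emulating dense
    tractography-derived networks, standard-format I/O (CSV matrix,
    edge list, GraphML) and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
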