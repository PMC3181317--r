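Package: diffpcor
Title: Differential Partial-Correlation Networks for Metabolic Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers per-condition association networks from shrinkage
    estimates of partial correlations (Ledoit-Wolf optimal shrinkage
    intensity with an identity correlation target), tests every variable
    pair for a between-group change in partial correlation with a
    label-permutation test, classifies significant changes (increase,
    decrease, sign change), and characterizes the resulting networks
    through topological properties (degree distribution, betweenness
    centrality, clustering coefficient). Includes a block-structured
    Gaussian graphical model simulator emulating lipoprotein-subclass
    panels, a nonparametric per-variable concentration screen, and a
    command-line pipeline with reproducible, logged runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
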