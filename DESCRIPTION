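Package: phenotraject
Title: Phenotype Trajectories from Label-Free 3D Culture Time-Lapse Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies co-occurring morphological states and recurring
    phenotype trajectories in multi-day time-lapse imaging of 3D cultures
    (spheroids, organoids) from tracked-object feature tables such as those
    exported by CellProfiler. Provides tracking-label correction for object
    splits, density-equalising geometric sketching, graph-based community
    detection of morphological states, reconstruction and clustering of
    per-object temporal state sequences via multiple correspondence
    analysis, trajectory motifs and state-transition summaries,
    representative-object and representative-outline selection via boundary
    power spectra, and replicate-stratified enrichment statistics
    (Cochran-Mantel-Haenszel, Breslow-Day, Woolf). A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    igraph,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    EBImage,
    png,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
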