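Package: dualstab
Title: Structure-Informed Prioritization of Missense Variants from
    Dual-Conformation Stability Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes protein missense variants by combining
    sequence-based pathogenicity scores with predicted stability changes
    of two conformational states (an active "open" and an autoinhibited
    "closed" state, as in Janus kinases). Provides in silico saturation
    mutagenesis over a protein sequence, ingestion of heterogeneous
    predictor score tables and dual-state free-energy-change tables,
    feature standardization, k-nearest-neighbor graph construction,
    two-way unsupervised clustering with enrichment-based cluster
    labeling against a population variant catalog, nearest-centroid
    classification of query variants, and structural-geometry analyses
    (rigid-body superposition with outlier pruning, domain-interface
    residues, residue contacts, binding-pocket distances, and
    per-residue fluctuation over coordinate ensembles). A seeded
    synthetic-data generator emulates the two-population feature
    structure the method assumes, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
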