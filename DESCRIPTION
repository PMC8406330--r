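Package: fbmnr
Title: Feature-Based Molecular Networking and Coculture Enrichment Screening
    for Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for untargeted LC-MS/MS metabolomics of microbial
    monocultures and cocultures. Implements GNPS-style spectral filtering
    (precursor-region removal, windowed top-k peak selection), the modified
    cosine similarity with matched-peak counting, molecular network
    construction with score and matched-peak thresholds, mutual top-k edge
    pruning and molecular-family size capping, spectral library matching,
    cross-polarity network merging by adduct-corrected neutral mass,
    per-file row-sum normalization, a replicate-consistent coculture
    enrichment screen (fold change plus one-tailed pooled-variance t), a
    three-way hue and transparency node encoding for multi-condition
    networks, and a deterministic synthetic LC-MS/MS data generator with
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'fbmnr-package.R'
    'io.R'
    'merge.R'
    'network.R'
    'pipeline.R'
    'quantify.R'
    'spectral.R'
    'synthetic.R'
    'viz.R'
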