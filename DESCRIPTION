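Package: mirloop
Title: Nutrient-Modulated miRNA-TF-mRNA Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers nutrient-modulated miRNA-TF-mRNA regulatory networks
    from paired miRNA/mRNA expression profiles of unreplicated RNA-seq
    libraries. Provides RPKM/CPM quantification with abundance filtering,
    Fisher's-exact differential expression calling with fold-change
    thresholds, a seed-weighted Smith-Waterman miRNA target scanner with a
    nearest-neighbor duplex free-energy model, miRNA-mRNA anticorrelation
    filtering, transcription-factor coexpression loop expansion, network
    assembly and export, and a fully seeded synthetic-data generator with
    planted ground truth for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
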