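Package: skincomet
Title: Charting Host-Microbe Co-Metabolism in Skin Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and calibrates clade-specific profile hidden Markov models
    for curated skin-aging gene modules, quantifies those modules in bacterial
    genomes, metagenome gene catalogs and 16S-inferred functional profiles, and
    relates pathway-level abundances to a phenotype-derived skin-aging score
    via constrained ordination (RDA) with permutation tests and per-pathway
    linear models. Includes orthologous-group inference across reference
    proteomes, progressive multiple sequence alignment, a neighbor-joining
    panel phylogeny, and a synthetic-data generator with recorded ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
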