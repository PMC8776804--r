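Package: flavoscope
Title: Taxonomy, Bloom Detection and CRISPR Host Linking for Phage Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for cultivated phage communities, built around
    marine flavophages (phages infecting Flavobacteriia). Implements
    whole-genome intergenomic similarity with strain/species/genus demarcation
    at the 100/95/70 percent thresholds, protein-cluster content distances with
    complete-linkage trees, bootstrap supports, 0.9-distance viral genome
    clusters (VGCs) and silhouette widths, per-family core gene sets,
    coverage/identity presence calling in metagenome read mappings with
    normalized abundances and phage/host ratios, and CRISPR spacer matching
    under gap and mismatch constraints. A synthetic-community generator with
    planted taxonomic tiers, simulated reads and planted spacers makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    IRanges,
    ape,
    Biostrings,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    Rsamtools,
    GenomicAlignments
Config/testthat/edition: 3
RoxygenNote: 7.3.3
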