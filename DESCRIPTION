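Package: coregenes
Title: Recursive Core-Gene Discovery and Comparative Microbial Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies core gene families (genes ubiquitous within a microbial
    clade at the nucleotide level) by a recursive, bottom-up ortholog search
    over a user-supplied guide taxonomy, and provides the downstream
    comparative machinery: nucleotide homology search with blastn-like
    thresholds, per-clade core family catalogs with paralog capture and
    representative selection, sequence and functional (COG-profile)
    phylogenies, a percentile co-clustering tree distance with a
    leaf-shuffling permutation null, phylogenetic alpha-diversity,
    inter/intra-clade distance ratios, hypergeometric functional-category
    enrichment, and a seeded synthetic pangenome generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
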