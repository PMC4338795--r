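Package: ppicurate
Title: Curation and Evidence Analysis of Single-Protein Interactomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to curate the experimentally supported interactome of a
    single query protein from database exports in PSI-MI TAB 2.7 and BioGRID
    TAB 2.0 layouts. Implements spoke-expansion removal, taxon filtering,
    within-publication deduplication, harmonized cross-database merging,
    a four-tier evidence classification of interactors, in-house Gene
    Ontology over-representation analysis (hypergeometric test with
    Bonferroni correction, top-N and p-value threshold modes) with
    contributor-set intersection and significance-level composition
    summaries, residue-level profiling of self-interaction evidence, and
    overlap of the interactome with GWAS risk loci via base-pair windows.
    A seeded synthetic-data generator produces every input format with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, NetworkBiology, Proteomics, GeneSetEnrichment, GO
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
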