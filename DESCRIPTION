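Package: coremgc
Title: Core Metabolic Gene Cluster Extraction from Annotated Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and extracts intact core metabolic gene clusters (MGCs)
    from cluster-annotated microbial genomes. Reads annotator-produced GenBank
    flat files, matches cluster member genes by keyword against gene names and
    products, chains matches by gene proximity (synteny) under a configurable
    gap budget, classifies chains as intact, candidate or rejected, attaches
    seven-rank taxonomy, filters protein sequences by reference-length
    coverage, dereplicates at 100 percent identity, and computes per-taxon
    prevalence and coexistence statistics over genome batches. Includes a
    seeded synthetic fixture generator that emulates annotator output with
    planted clusters and a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
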