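Package: cpmarker
Title: Chloroplast Genome InDel Marker Discovery and In Silico Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of plastid (chloroplast) genomes for the
    development of species-diagnostic InDel markers, with in silico
    authentication assays. Implements sliding-window nucleotide diversity
    (Nei's pi) scans with hypervariable hotspot calling, quadripartite
    genome partitioning (LSC/SSC/IRa/IRb), InDel and tandem-repeat event
    extraction from multiple alignments, marker definition with per-haplotype
    PCR product-size prediction, in silico PCR (mismatch-tolerant primer
    binding with a 3' anchor rule), restriction digestion including Type IIS
    offset cutters, and fragment-pattern species classification. A seedable
    synthetic-data generator produces truth-bearing genome quartets and
    market-sample panels for end-to-end validation without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
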