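Package: m6dAtools
Title: Genome-Wide Characterization of N6-Methyldeoxyadenosine from
    SMRT-Seq Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing N6-methyldeoxyadenosine (m6dA) in
    genomes from single-molecule real-time (SMRT) sequencing kinetics.
    Calls strand-specific m6dA sites from inter-pulse-duration (IPD)
    summaries with coverage and IPD-ratio filters, estimates per-site
    methylated fractions from per-molecule kinetics with a two-component
    mixture model, and characterizes the resulting site sets: chromosome
    and genomic-feature enrichment by permutation testing against a
    deoxyadenosine shuffle universe, dinucleotide and combined-motif
    enrichment against a failed-filter null set, detection of dense m6dA
    clusters, haplotype-resolved differential methylation, family-trio
    overlap and relatedness tests, and the association between genic m6dA
    and gene expression including allele-specific expression. A seeded
    synthetic-data generator produces ground-truthed toy genomes,
    kinetics, haplotypes, trios and expression tables so every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
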