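Package: minikaryo
Title: Comparative Analysis of Fragmented Mitochondrial Minichromosome
    Karyotypes
Version: 0.1.0
Authors@R:
    person("Mini", "Karyo", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative study of fragmented animal
    mitochondrial genomes composed of circular minichromosomes, as found
    in sucking lice (Anoplura).  Provides a compact karyotype grammar and
    parser, pairwise karyotype comparison, parsimony inference of
    inter-minichromosomal recombination events (mergers, translocations,
    duplications, degenerations, deletions) with per-location minimum
    event bounds and hotspot tallies, sequence-level evidence utilities
    (alignment percent difference, longest shared identical stretch with
    a Monte Carlo chance null, conserved non-coding-region motif
    discovery), a synthetic minichromosomal genome and paired-end read
    simulator with ground-truth event logs, and a toy iterative
    map-to-reference assembler with non-coding-region bait recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
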