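Package: codonscape
Title: Comparative Codon-Level Selection and Conservation Analysis for
    Bacterial Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution analysis of bacterial
    protein-coding gene families, built around multi-spanning membrane-protein
    families such as the TatC component of the twin-arginine translocase.
    Constructs codon alignments by back-translating protein alignments onto
    coding sequences, computes pairwise synonymous/non-synonymous substitution
    statistics by Nei-Gojobori pathway counting with Jukes-Cantor correction
    and a saturation guard, profiles per-codon synonymous substitutions and
    per-column consensus conservation with sub-group comparison, derives
    consensus transmembrane regions from multiple per-residue predictions,
    maps gene-association frequencies in fixed-size neighborhoods around
    focal loci, and summarises selection regimes per group. A synthetic-data
    generator produces codon alignments evolved at a controlled dN/dS along a
    tree, annotation tables with planted neighborhood gene frequencies, and
    multi-spanning membrane proteins with known transmembrane intervals, so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
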