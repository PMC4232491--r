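Package: ncxminer
Title: Mining and Molecular Evolution of Na+/Ca2+ Exchanger Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for desk-scale mining of the Na+/Ca2+ exchanger
    superfamily (NCX, NCKX, CCX/NCLX) in predicted proteomes: degenerate
    alpha-repeat motif matching and position-specific weight matrix (PSWM)
    construction and scanning, rule-based subtype classification from motif
    and InterPro/Pfam domain evidence, reciprocal-best-hit ortholog pairing
    with Smith-Waterman alignment, codon-aware back-translation of protein
    alignments, sliding-window nucleotide diversity (pi) and Nei-Gojobori
    (1986) counting dN/dS, and in-silico PCR with tandem gene-model bridging
    for re-annotation of split gene predictions. Includes synthetic-data
    generators for every stage and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
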