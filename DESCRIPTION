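Package: orfdecay
Title: Inferring De Novo Gene Origin from Non-Coding Homologous Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether a protein-coding gene arose de novo
    from non-protein-coding DNA. Provides candidate filtering over tabular
    homology hits, reconstruction of putative open reading frames by mapping
    a reference gene's coding exons into homologous genomic regions,
    detection and classification of ORF disablers (start/stop-codon loss,
    premature stop codons, frame-shifting indels) by artificial translation,
    cross-taxon shared-disabler analysis with parsimony reconstruction of
    coding-ability gains and losses on a species tree, distance-based
    phylogenetics (Kimura two-parameter and Tamura-Nei distances,
    neighbor-joining, bootstrap), windowed dot-plot repeat detection,
    anchor-based synteny-block comparison, and a fully seeded sequence
    evolution simulator that generates ground-truth scenarios for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    methods,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
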