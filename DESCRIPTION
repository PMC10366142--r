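Package: puncta
Title: Quantification of Nuclear Condensates from Fluorescence Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intranuclear biomolecular condensates from
    single-plane fluorescence micrographs: empty-well background subtraction
    and flat-field illumination correction, speckle enhancement, two-round
    condensate identification (adaptive Robust Background followed by global
    Otsu with a correction factor), per-object size/shape/intensity
    measurement, large-condensate cell classification, and Pearson
    colocalization. A second stage calls large genomic domains from ChIP-seq
    domain sizes by a rank-slope crossing criterion (or a fixed 96-kb cutoff)
    and computes randomization-based gene-set overlap statistics
    (representation factor, hypergeometric enrichment). A synthetic-data
    generator produces ground-truthed micrographs, heavy-tailed domain-size
    lists and gene universes with planted overlaps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
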