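Package: trvar
Title: Comparative Analysis of Tandem Repeat Length Variation Between Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects tandem repeats (TRs) in assembled genomes with a
    TRF-style wraparound alignment score, removes redundant calls, anchors
    each repeat in a second genome by its unique flanking sequence, calls
    length-variable repeats, identifies those that alter coding sequence and
    protein length, polarizes gains and losses against an outgroup, classifies
    per-individual allele-length panels, and computes category-enrichment
    folds from contingency counts. Ships a synthetic genome-trio simulator
    with planted, evolving repeat loci and full ground truth so the whole
    pipeline is testable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, Alignment, ComparativeGenomics,
    RepeatAnalysis
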