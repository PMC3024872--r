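Package: jxpepdb
Title: Splice-Junction Peptide Databases and MS-Based Validation of
    Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteogenomics toolkit for validating alternative-splice forms
    observed in RNA-Seq data with shotgun mass-spectrometry evidence. Builds
    translated junction-peptide databases from splice-junction intervals
    (exon-flank extraction, six-frame translation, junction-spanning ORF
    selection), quantifies in silico which junctions are identifiable by
    tryptic peptides of MS-compatible length, post-processes peptide-spectrum
    matches with target-decoy and class-specific (novel-subset) false
    discovery rate control plus a mismatch-distance homology filter, and
    relates MS detection probability to transcript abundance (RPKM). Includes
    seeded synthetic-data generators with planted ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
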