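Package: cugusage
Title: Conservation-Based Assignment of CUG Codon Translation in Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns the translation of the CUG codon (leucine under the
    standard genetic code versus serine under the alternative yeast codon
    usage) to yeast species from curated protein multiple sequence
    alignments and their spliced coding sequences. Maps codons onto
    alignment columns, scores per-column conservation with a
    property-entropy measure under a focal subalignment protocol, labels
    conserved leucine and serine positions at several thresholds, tallies
    per-species CUG placement and calls the codon usage scheme, computes
    the pairwise shared-CUG-position matrix, writes CUG-masked alignments
    for code-agnostic tree inference, and ships a synthetic-data generator
    with ground-truth bookkeeping for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
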