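Package: amplitag
Title: Combinatorial Inline Indexing for Illumina Amplicon Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and validation of variable-length internal (inline)
    index sets with heterogeneity spacers for Illumina amplicon
    sequencing; assembly of TruSeq- and Nextera-compatible indexed
    fusion-primer panels and 96-well combinatorial plate layouts;
    demultiplexing of combinatorially quadruple-indexed paired-end
    reads with tag-jump reporting; molarity-aware library pooling
    calculations; per-method library-preparation cost and PCR-count
    planning; and a synthetic paired-end read simulator with ground
    truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
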