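Package: barmerge
Title: Paired-End Read Merging and DNA Barcode Finishing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges overlapping paired-end reads with a seed-and-extend
    overlap scan that tolerates both substitutions and indels, resolving
    conflicting bases by Phred quality. Includes the surrounding DNA-barcode
    finishing stages: sliding-window quality trimming and filtering of FASTQ
    input, per-run quality reports, six-frame stop-codon and frameshift
    correction for coding barcodes, a paired-read simulator with a
    quality-dependent error model, and an alignment-based evaluation harness
    that scores merged sequences against a reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
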