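Package: bioshade
Title: Streaming Syntax Highlighting for Biological Plain-Text Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming syntax highlighter for the plain-text file formats of
    computational biology. Lexes FASTA, FASTQ, SAM, VCF, BED6, GTF, PDB and
    CLUSTAL lines into a unified system of biological style classes
    (genomic coordinates, read names, CIGAR operations, per-base nucleotide
    and amino-acid classes, quality-gradient bins) and renders them as
    ANSI-coloured terminal output suitable for a pager, or as HTML. Ships an
    additive IUPAC nucleotide colour scheme in which ambiguity codes are
    mixed from the four primary base colours, PHRED quality gradients,
    published amino-acid colour schemes, a colour-blind high-contrast theme
    validated under simulated dichromacy, and seeded generators that produce
    small valid example files in every supported format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
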