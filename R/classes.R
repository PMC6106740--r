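# The closed set of biological style classes. One class per biological
# meaning across formats: a genomic coordinate lexes to the same class
# whether it came from BED, GTF, SAM or VCF, so one colour can be reserved
# for it everywhere.

iupac_codes <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

aa_codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

cigar_class_of_op <- c(
  "M" = "cigar.match",     "=" = "cigar.match",   "X" = "cigar.mismatch",
  "I" = "cigar.insertion", "D" = "cigar.deletion", "N" = "cigar.skip",
  "S" = "cigar.clip",      "H" = "cigar.clip",     "P" = "cigar.pad"
)

n_quality_bins <- 6L

#' Enumerate the biological style classes
#'
#' Every token emitted by any lexer carries one of these classes; every
#' theme maps each of them to a colour (or to "no styling"). The set is
#' closed: formats share classes wherever the biological meaning is shared.
#'
#' @return A character vector of class identifiers.
#' @examples
#' head(style_classes())
#' "coordinate" %in% style_classes()
#' @export
style_classes <- function() {
  c(
    "coordinate", "sample-info", "read-name", "flag", "strand",
    "record-type", "meta-key", "meta-value", "comment", "unknown",
    unique(unname(cigar_class_of_op)),
    paste0("nucleotide.", iupac_codes),
    paste0("aminoacid.", aa_codes),
    paste0("quality.", seq_len(n_quality_bins) - 1L),
    "feature.cds", "feature.utr", "feature.start-codon",
    "feature.stop-codon", "feature.other"
  )
}
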