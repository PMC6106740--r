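# Supported format identifiers. PLAIN means "pass through unhighlighted".

#' Format identifiers
#'
#' @return Character vector of the nine recognised format ids.
#' @examples
#' format_ids()
#' @export
format_ids <- function() {
  c("FASTA", "FASTQ", "SAM", "VCF", "BED", "GTF", "PDB", "CLUSTAL", "PLAIN")
}

extension_formats <- c(
  fa = "FASTA", fasta = "FASTA", fna = "FASTA", faa = "FASTA",
  fq = "FASTQ", fastq = "FASTQ",
  sam = "SAM", vcf = "VCF", bed = "BED", gtf = "GTF",
  pdb = "PDB", ent = "PDB",
  aln = "CLUSTAL", clustal = "CLUSTAL"
)

#' Detect the format of a file or stream
#'
#' Format assignment follows the same precedence a user expects from a
#' pager wrapper: a recognised file extension wins (a trailing `.gz` is
#' stripped first); otherwise the first lines of content are sniffed for
#' the formats' signatures (`##fileformat=VCF`, `@HD`/`@SQ` header tags,
#' the `CLUSTAL` banner, a `>` FASTA header, an `@`-led 4-line FASTQ
#' cycle, PDB `HEADER`/`ATOM` records, and the tab-field shapes of
#' BED/GTF/SAM bodies). Anything unrecognised is `PLAIN` — detection never
#' fails, it only falls through.
#'
#' @param path_hint A file name to take an extension from, or `NULL`.
#' @param first_lines Character vector of leading content lines (may be
#'   empty).
#' @return A single format id (see [format_ids()]).
#' @examples
#' detect_format("NA12878.sam")
#' detect_format(NULL, "##fileformat=VCFv4.2")
#' detect_format("notes.txt", "hello")
#' @export
detect_format <- function(path_hint = NULL, first_lines = character()) {
  if ((is.null(path_hint) || !nzchar(path_hint)) && length(first_lines) == 0) {
    stop("need a path hint or content lines", call. = FALSE)
  }
  if (!is.null(path_hint) && nzchar(path_hint)) {
    base <- sub("\\.gz$", "", basename(path_hint), ignore.case = TRUE)
    ext <- tolower(sub(".*\\.", "", base))
    if (grepl(".", base, fixed = TRUE) && ext %in% names(extension_formats)) {
      return(unname(extension_formats[ext]))
    }
  }
  sniff_content(first_lines)
}

sniff_content <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return("PLAIN")
  first <- lines[1]
  if (startsWith(first, "##fileformat=VCF")) return("VCF")
  if (grepl("^@(HD|SQ|RG|PG|CO)\t", first)) return("SAM")
  if (grepl("^CLUSTAL", first)) return("CLUSTAL")
  if (startsWith(first, ">")) return("FASTA")
  if (startsWith(first, "@")) {
    # FASTQ cycle: @title / sequence / + / quality of equal length
    if (length(lines) >= 4 && startsWith(lines[3], "+") &&
        grepl("^[A-Za-z.~-]+$", lines[2]) &&
        nchar(lines[2]) == nchar(lines[4])) {
      return("FASTQ")
    }
    if (length(lines) < 4) return("FASTQ")  # plausible start of a record
  }
  if (grepl("^(HEADER|TITLE |COMPND|ATOM  |HETATM|REMARK)", first)) return("PDB")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) > 0) {
    f <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    num <- function(i) grepl("^[0-9]+$", f[i])
    if (length(f) >= 11 && num(4) && num(5) &&
        !is.na(f[6]) && grepl("^(\\*|[0-9]+[MIDNSHP=X]+)", f[6])) {
      return("SAM")
    }
    if (length(f) >= 9 && num(4) && num(5) && f[7] %in% c("+", "-", ".")) {
      return("GTF")
    }
    if (length(f) >= 3 && length(f) <= 12 && num(2) && num(3)) return("BED")
  }
  "PLAIN"
}

#' Guess whether sequence lines are nucleotide or amino acid
#'
#' Looks at up to the first 10,000 residue characters (gap characters
#' `-`, `.`, `*` and whitespace are ignored) and calls the content
#' nucleotide when at least 90% of residues are in \{A, C, G, T, U, N\}
#' (either case); otherwise amino acid. The threshold tolerates occasional
#' ambiguity codes in DNA while still catching protein sequences, whose
#' composition rarely exceeds ~50% of those six letters.
#'
#' @param sequence_lines Character vector of sequence lines.
#' @return `"nucleotide"` or `"aminoacid"`.
#' @examples
#' sniff_alphabet("ACGTACGTNN")
#' sniff_alphabet("MKVLWAALLVTFLAGCQA")
#' @export
sniff_alphabet <- function(sequence_lines) {
  chars <- unlist(strsplit(sequence_lines, "", fixed = TRUE), use.names = FALSE)
  chars <- chars[!chars %in% c("-", ".", "*", " ", "\t")]
  if (length(chars) == 0) stop("no residue characters to examine", call. = FALSE)
  chars <- chars[seq_len(min(length(chars), 10000L))]
  frac <- mean(toupper(chars) %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.90) "nucleotide" else "aminoacid"
}
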