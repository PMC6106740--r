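tok_df <- function(...) tibble::tibble(...)

test_that("SAM header lines split into record-type, keys and values", {
  st <- lex_state("SAM")
  r <- lex_line(st, "@SQ\tSN:chr1\tLN:248956422")
  expect_identical(
    as.data.frame(r$tokens),
    as.data.frame(tok_df(
      start = c(0L, 4L, 7L, 12L, 15L),
      end = c(3L, 6L, 11L, 14L, 24L),
      class = c("record-type", "meta-key", "meta-value", "meta-key",
                "meta-value"))))
  expect_true(r$state$in_header)
  # sample names in read groups get the sample-info class
  r2 <- lex_line(st, "@RG\tID:rg1\tSM:NA12878")
  expect_true("sample-info" %in% r2$tokens$class)
  # @CO free text is one comment span
  r3 <- lex_line(st, "@CO\tanything at all\tincluding tabs")
  expect_identical(r3$tokens$class, c("record-type", "comment"))
})

test_that("SAM body fields carry their biological classes", {
  st <- lex_state("SAM")
  line <- paste("r1", "99", "chr7", "100", "60", "8M2I4M", "=", "200", "114",
                "ACGTACGTACGTAC", "IIIIIIIIIIIIII", "NM:i:1", sep = "\t")
  r <- lex_line(st, line)
  expect_false(r$state$in_header)
  tk <- r$tokens
  cls_of <- function(txt) {
    i <- which(substring(line, tk$start + 1, tk$end) == txt)
    tk$class[i]
  }
  expect_identical(cls_of("r1"), "read-name")
  expect_identical(cls_of("99"), "flag")
  expect_identical(cls_of("chr7"), "coordinate")
  expect_identical(cls_of("8M"), "cigar.match")
  expect_identical(cls_of("2I"), "cigar.insertion")
  expect_identical(cls_of("4M"), "cigar.match")
  expect_identical(cls_of("NM:i"), "meta-key")
  # TLEN (114) carries no token
  expect_length(cls_of("114"), 0)
  # per-base SEQ tokens and per-char QUAL tokens
  expect_identical(sum(startsWith(tk$class, "nucleotide.")), 14L)
  expect_identical(sum(startsWith(tk$class, "quality.")), 15L)  # + MAPQ
  # '=' in SEQ takes the fully ambiguous class
  r2 <- lex_line(r$state, sub("ACGTACGTACGTAC", "AC=TACGTACGTAC", line))
  seqs <- r2$tokens[startsWith(r2$tokens$class, "nucleotide."), ]
  expect_identical(seqs$class[3], "nucleotide.N")
})

test_that("header state never returns once a body line is seen", {
  st <- lex_state("SAM")
  st <- lex_line(st, "@HD\tVN:1.5")$state
  expect_true(st$in_header)
  body <- paste(c("r", "0", "*", "0", "0", "*", "*", "0", "0", "*", "*"),
                collapse = "\t")
  st <- lex_line(st, body)$state
  expect_false(st$in_header)
  # an @-line now lexes as (malformed) body, not as header
  r <- lex_line(st, "@SQ\tSN:chr1\tLN:1")
  expect_false(r$state$in_header)
  expect_false("record-type" %in% r$tokens$class)
})

test_that("VCF meta, column header and body classify per field", {
  st <- lex_state("VCF")
  r1 <- lex_line(st, "##fileformat=VCFv4.2")
  expect_identical(r1$tokens$class, c("meta-key", "meta-value"))
  r2 <- lex_line(r1$state, "#CHROM\tPOS\tID\tREF\tALT")
  expect_identical(r2$tokens$class, "record-type")
  line <- paste("chr1", "123456", "rs42", "A", "G,T", "99.5", "PASS",
                "DP=30;AF=0.5;DB", "GT:DP", "0/1:28", sep = "\t")
  r3 <- lex_line(r2$state, line)
  tk <- r3$tokens
  txt <- substring(line, tk$start + 1, tk$end)
  expect_identical(tk$class[txt == "chr1"], "coordinate")
  expect_identical(tk$class[txt == "123456"], "coordinate")
  expect_length(tk$class[txt == "rs42"], 0)   # ID unstyled
  expect_length(tk$class[txt == "PASS"], 0)   # FILTER unstyled
  expect_identical(tk$class[txt == "DP"], "meta-key")
  expect_identical(tk$class[txt == "DB"], "meta-key")  # INFO flag
  expect_identical(tk$class[txt == "0.5"], "meta-value")
  expect_identical(tk$class[txt == "GT:DP"], "sample-info")
  expect_identical(tk$class[txt == "0/1:28"], "sample-info")
  # REF/ALT per base; the comma is unstyled
  expect_identical(sum(startsWith(tk$class, "nucleotide.")), 3L)
  expect_true(startsWith(tk$class[txt == "99.5"], "quality."))
})

test_that("BED and GTF share the coordinate class and GTF features set bg", {
  st <- lex_state("BED")
  line <- "chr5\t1000\t2000\tregion1\t960\t+"
  tk <- lex_line(st, line)$tokens
  expect_identical(tk$class,
                   c("coordinate", "coordinate", "coordinate", "read-name",
                     "quality.5", "strand"))
  stg <- lex_state("GTF")
  gline <- paste("chr5", "src", "CDS", "1000", "2000", ".", "+", "0",
                 'gene_id "g1"; transcript_id "t1";', sep = "\t")
  r <- lex_line(stg, gline)
  expect_identical(attr(r$tokens, "line_class"), "feature.cds")
  tk <- r$tokens
  txt <- substring(gline, tk$start + 1, tk$end)
  expect_identical(tk$class[txt == "CDS"], "feature.cds")
  expect_identical(tk$class[txt == "gene_id"], "meta-key")
  expect_identical(tk$class[txt == "\"g1\""], "meta-value")
  # non-coding features carry no line background
  r2 <- lex_line(stg, sub("\tCDS\t", "\texon\t", gline))
  expect_null(attr(r2$tokens, "line_class"))
})

test_that("PDB ATOM records classify by fixed columns", {
  st <- lex_state("PDB")
  line <- paste0("ATOM      1  CA AALA A  42    ",
                 "  11.104  13.207   9.100  1.00 77.00           C")
  r <- lex_line(st, line)
  tk <- r$tokens
  txt <- substring(line, tk$start + 1, tk$end)
  expect_identical(tk$class[txt == "ATOM"], "record-type")
  expect_identical(tk$class[txt == "CA"][1], "meta-key")
  expect_identical(tk$class[txt == "ALA"], "meta-value")
  # B-factor 77.00 in cols 61-66 -> top-half gradient bin
  expect_identical(tk$class[txt == "77.00"], "quality.4")
  # occupancy (cols 55-60) is unstyled
  expect_length(tk$class[txt == "1.00"], 0)
})

test_that("FASTA sniffs its alphabet and emits per-residue tokens", {
  st <- lex_state("FASTA")
  r <- lex_line(st, ">chr1 human")
  expect_identical(r$tokens$class, "read-name")
  r2 <- lex_line(r$state, "ACGN")
  expect_identical(
    as.data.frame(r2$tokens),
    as.data.frame(tok_df(start = 0:3, end = 1:4,
                         class = paste0("nucleotide.", c("A", "C", "G", "N")))))
  expect_identical(r2$state$fasta_alphabet, "nucleotide")
  # amino-acid FASTA flips the alphabet and keeps gaps unstyled
  sta <- lex_line(lex_state("FASTA"), ">prot")$state
  r3 <- lex_line(sta, "MKV-LW")
  expect_identical(r3$state$fasta_alphabet, "aminoacid")
  expect_identical(r3$tokens$class,
                   paste0("aminoacid.", c("M", "K", "V", "L", "W")))
})

test_that("FASTQ cycles through its four phases", {
  st <- lex_state("FASTQ")
  r1 <- lex_line(st, "@read1")
  expect_identical(r1$tokens$class, "read-name")
  r2 <- lex_line(r1$state, "ACGT")
  expect_identical(sum(startsWith(r2$tokens$class, "nucleotide.")), 4L)
  r3 <- lex_line(r2$state, "+")
  expect_identical(r3$tokens$class, "comment")
  r4 <- lex_line(r3$state, "II!~")
  expect_identical(r4$tokens$class,
                   c("quality.5", "quality.5", "quality.0", "quality.5"))
  expect_identical(r4$state$record_phase, 0L)
})

test_that("CLUSTAL names, residues and conservation lines classify", {
  st <- lex_state("CLUSTAL")
  r0 <- lex_line(st, "CLUSTAL W (1.83) multiple sequence alignment")
  expect_identical(r0$tokens$class, "record-type")
  r1 <- lex_line(r0$state, "seq01    MKV-LW 6")
  cls <- r1$tokens$class
  expect_identical(cls[1], "read-name")
  expect_identical(sum(startsWith(cls, "aminoacid.")), 5L)
  expect_identical(cls[length(cls)], "meta-value")
  r2 <- lex_line(r1$state, "         ** :.")
  expect_identical(r2$tokens$class, "comment")
})

test_that("genomic coordinates lex to one shared class in all four formats", {
  seen <- character()
  for (fmt in c("BED", "GTF", "SAM", "VCF")) {
    tk <- lex_all(generate_fixture(fmt, seed = 2), fmt)
    coord <- tk[tk$class == "coordinate", ]
    expect_gt(nrow(coord), 0, label = fmt)
    seen <- c(seen, unique(coord$class))
  }
  expect_identical(unique(seen), "coordinate")
})

test_that("blank and carriage-return-only lines yield no zero-width tokens", {
  for (fmt in setdiff(format_ids(), "PLAIN")) {
    for (ln in c("", "\r")) {
      tk <- lex_line(lex_state(fmt), ln)$tokens
      expect_true(all(tk$end > tk$start), label = paste(fmt, deparse(ln)))
    }
  }
})

test_that("a trailing carriage return is never part of a token", {
  st <- lex_state("BED")
  line <- "chr1\t5\t10\r"
  tk <- lex_line(st, line)$tokens
  expect_true(all(tk$end <= nchar(line) - 1))
  out <- render_ansi(line, tk, shade_theme("default"))
  expect_identical(strip_ansi(out), line)
})

test_that("multi-byte UTF-8 content yields byte offsets that never split a character", {
  st <- lex_state("SAM")
  line <- "@CO\trésumé 世界"
  r <- lex_line(st, line)
  nb <- nchar(line, type = "bytes")
  expect_true(all(r$tokens$end <= nb))
  # the comment token must cover the full multibyte tail
  expect_identical(max(r$tokens$end), nb)
  out <- render_ansi(line, r$tokens, shade_theme("default"))
  expect_identical(strip_ansi(out), line)
})

test_that("lexing any byte garbage stays total, sorted and in bounds", {
  withr::local_seed(2024)
  formats <- setdiff(format_ids(), "PLAIN")
  for (i in 1:400) {
    fmt <- formats[(i %% length(formats)) + 1]
    st <- lex_state(fmt)
    ln <- if (i %% 2 == 0) fuzz_bytes() else fuzz_fields()
    r <- lex_line(st, ln)
    tk <- r$tokens
    nb <- nchar(ln, type = "bytes")
    expect_true(all(tk$start >= 0 & tk$end <= nb & tk$start < tk$end))
    if (nrow(tk) > 1) {
      expect_true(all(diff(tk$start) > 0))
      expect_true(all(tk$start[-1] >= tk$end[-nrow(tk)]))
    }
    expect_true(all(tk$class %in% style_classes()))
  }
})
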