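# Seeded generators of small, well-formed example files in every supported
# format. They stand in for downloaded example data: tests and docs can
# produce valid input of any size on demand, reproducibly.

#' Generate a synthetic file in a supported format
#'
#' Produces a small, format-valid file deterministically from `(format,
#' params, seed)`. The files emulate the *shape* of real data — header
#' sections, consistent field widths, per-position FASTQ quality decay, a
#' configurable fraction of PCR-duplicate reads in SAM (identical sequence
#' and position, duplicate FLAG bit set), coding features in GTF,
#' fixed-column PDB ATOM records — not its biology: there is no reference
#' genome and no alignment semantics.
#'
#' Sequences use the full 16-letter IUPAC alphabet at a low ambiguity rate
#' (`ambiguity`, default 2%) so that every nucleotide colour path is
#' exercised.
#'
#' @param format A format id (see [format_ids()]), not `"PLAIN"`.
#' @param params Named list of generator parameters; unset entries take
#'   the defaults listed below. Common ones: `n_records`, `read_length`,
#'   `gc_fraction`, `ambiguity`, `dup_fraction` (SAM), `n_samples` (VCF),
#'   `n_genes` (GTF), `n_seqs`/`aln_length` (CLUSTAL), `alphabet` (FASTA).
#' @param seed Integer seed; identical calls are byte-identical.
#' @return A character vector of lines.
#' @examples
#' sam <- generate_fixture("SAM", list(n_records = 5), seed = 1)
#' head(sam)
#' @export
generate_fixture <- function(format, params = list(), seed = 1L) {
  format <- match.arg(toupper(format), setdiff(format_ids(), "PLAIN"))
  if (!is.list(params)) stop("params must be a list", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  for (p in c("n_records", "read_length", "n_samples", "n_genes", "n_seqs",
              "aln_length", "seq_length", "n_atoms")) {
    if (!is.null(params[[p]]) &&
        (!is.numeric(params[[p]]) || params[[p]] < 0)) {
      stop("invalid param ", p, ": must be a non-negative number",
           call. = FALSE)
    }
  }
  for (p in c("gc_fraction", "ambiguity", "dup_fraction")) {
    if (!is.null(params[[p]]) &&
        (!is.numeric(params[[p]]) || params[[p]] < 0 || params[[p]] > 1)) {
      stop("invalid param ", p, ": must be in [0, 1]", call. = FALSE)
    }
  }
  withr::with_seed(as.integer(seed), {
    switch(format,
      FASTA = gen_fasta(params),
      FASTQ = gen_fastq(params),
      SAM = gen_sam(params),
      VCF = gen_vcf(params),
      BED = gen_bed(params),
      GTF = gen_gtf(params),
      PDB = gen_pdb(params),
      CLUSTAL = gen_clustal(params)
    )
  })
}

pget <- function(params, name, default) {
  if (is.null(params[[name]])) default else params[[name]]
}

ambiguity_codes <- setdiff(iupac_codes, c("A", "C", "G", "T", "U"))

# random nucleotide string with controlled GC and IUPAC ambiguity rate
rand_seq <- function(n, gc = 0.5, ambiguity = 0.02) {
  base <- sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  amb <- stats::runif(n) < ambiguity
  base[amb] <- sample(ambiguity_codes, sum(amb), replace = TRUE)
  paste(base, collapse = "")
}

rand_aa_seq <- function(n) {
  res <- setdiff(aa_codes, c("B", "Z", "X"))
  paste(sample(res, n, replace = TRUE), collapse = "")
}

# PHRED+33 quality string with per-position decay: q_i declines linearly
# from q_start at ~0.25 points/cycle with gaussian noise, clamped to [2, 40]
rand_qual <- function(n, q_start = 38, decay = 0.25, sd = 3) {
  q <- round(q_start - decay * (seq_len(n) - 1) + stats::rnorm(n, 0, sd))
  q <- pmin(40, pmax(2, q))
  intToUtf8(q + 33L)
}

gen_fasta <- function(params) {
  n <- pget(params, "n_records", 5L)
  len <- pget(params, "seq_length", 120L)
  alphabet <- pget(params, "alphabet", "nucleotide")
  gc <- pget(params, "gc_fraction", 0.5)
  amb <- pget(params, "ambiguity", 0.02)
  width <- pget(params, "width", 60L)
  out <- character(0)
  for (i in seq_len(n)) {
    s <- if (alphabet == "nucleotide") rand_seq(len, gc, amb)
         else rand_aa_seq(len)
    starts <- seq(1, nchar(s), by = width)
    out <- c(out,
             sprintf(">seq%03d synthetic %s record", i, alphabet),
             substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }
  out
}

gen_fastq <- function(params) {
  n <- pget(params, "n_records", 20L)
  len <- pget(params, "read_length", 50L)
  gc <- pget(params, "gc_fraction", 0.5)
  out <- character(4L * n)
  for (i in seq_len(n)) {
    seq_ <- rand_seq(len, gc, ambiguity = 0)
    # sprinkle N calls as real basecallers do
    if (stats::runif(1) < 0.2) {
      pos <- sample(len, 1)
      substr(seq_, pos, pos) <- "N"
    }
    out[4 * i - 3] <- sprintf("@read%05d/1", i)
    out[4 * i - 2] <- seq_
    out[4 * i - 1] <- "+"
    out[4 * i] <- rand_qual(len)
  }
  out
}

gen_sam <- function(params) {
  n <- pget(params, "n_records", 30L)
  len <- pget(params, "read_length", 50L)
  gc <- pget(params, "gc_fraction", 0.5)
  amb <- pget(params, "ambiguity", 0.02)
  dup <- pget(params, "dup_fraction", 0.1)
  ref_len <- 1000000L
  header <- c(
    "@HD\tVN:1.5\tSO:coordinate",
    sprintf("@SQ\tSN:chr1\tLN:%d", ref_len),
    "@RG\tID:rg1\tSM:sample01\tLB:lib1\tPL:ILLUMINA",
    "@PG\tID:gen\tPN:bioshade\tVN:0.1.0",
    "@CO\tsynthetic alignment fixture"
  )
  pos <- sort(sample.int(ref_len - len, n, replace = TRUE))
  body <- character(n)
  prev <- NULL
  cigars <- function() {
    r <- stats::runif(1)
    if (r < 0.6) {
      sprintf("%dM", len)
    } else if (r < 0.75) {
      a <- sample(5:(len - 10), 1)
      sprintf("%dM%dI%dM", a, 2L, len - a - 2L)
    } else if (r < 0.9) {
      a <- sample(5:(len - 10), 1)
      sprintf("%dS%dM", a, len - a)
    } else {
      a <- sample(5:(len - 10), 1)
      sprintf("%dM%dD%dM", a, sample(1:3, 1), len - a)
    }
  }
  for (i in seq_len(n)) {
    if (!is.null(prev) && stats::runif(1) < dup) {
      # PCR duplicate: same sequence and position, duplicate flag set
      body[i] <- sprintf(
        "read%05d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tRG:Z:rg1",
        i, bitwOr(prev$flag, 1024L), "chr1", prev$pos, prev$mapq,
        prev$cigar, prev$seq, prev$qual, prev$nm)
      next
    }
    rec <- list(
      flag = sample(c(0L, 16L), 1),
      pos = pos[i],
      mapq = sample(0:60, 1),
      cigar = cigars(),
      seq = rand_seq(len, gc, amb),
      qual = rand_qual(len),
      nm = sample(0:4, 1)
    )
    body[i] <- sprintf(
      "read%05d\t%d\tchr1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tRG:Z:rg1",
      i, rec$flag, rec$pos, rec$mapq, rec$cigar, rec$seq, rec$qual, rec$nm)
    prev <- rec
  }
  c(header, body)
}

gen_vcf <- function(params) {
  n <- pget(params, "n_records", 15L)
  n_samples <- pget(params, "n_samples", 2L)
  samples <- sprintf("SAMPLE%02d", seq_len(n_samples))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bioshade-fixture",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (n == 0) return(header)
  pos <- sort(sample.int(999999L, n))
  body <- vapply(seq_len(n), function(i) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    gts <- vapply(seq_len(n_samples), function(j) {
      sprintf("%s:%d", sample(c("0/0", "0/1", "1/1"), 1), sample(5:60, 1))
    }, character(1))
    paste(c("chr1", pos[i], sprintf("rs%06d", sample.int(999999L, 1)),
            ref, alt, sprintf("%.1f", stats::runif(1, 10, 99)), "PASS",
            sprintf("DP=%d;AF=%.3f", sample(10:120, 1), stats::runif(1)),
            "GT:DP", gts), collapse = "\t")
  }, character(1))
  c(header, body)
}

gen_bed <- function(params) {
  n <- pget(params, "n_records", 12L)
  starts <- sort(sample.int(999000L, n))
  vapply(seq_len(n), function(i) {
    w <- sample(50:900, 1)
    paste(c("chr1", starts[i], starts[i] + w,
            sprintf("region%03d", i), sample(0:1000, 1),
            sample(c("+", "-"), 1)), collapse = "\t")
  }, character(1))
}

gen_gtf <- function(params) {
  n_genes <- pget(params, "n_genes", 2L)
  out <- c("#!genome-build synthetic-1.0", "#!annotation-source bioshade")
  at <- 1000L
  for (g in seq_len(n_genes)) {
    attrs <- function(extra = "") {
      sprintf("gene_id \"GENE%03d\"; transcript_id \"GENE%03d.1\";%s",
              g, g, extra)
    }
    strand <- sample(c("+", "-"), 1)
    utr5 <- c(at, at + 119L)
    cds1 <- c(at + 120L, at + 320L)
    cds2 <- c(at + 500L, at + 700L)
    utr3 <- c(at + 701L, at + 820L)
    row <- function(feature, s, e, frame = ".", extra = "") {
      paste(c("chr1", "bioshade", feature, s, e,
              sample(0:1000, 1), strand, frame, attrs(extra)),
            collapse = "\t")
    }
    out <- c(out,
      row("gene", utr5[1], utr3[2]),
      row("transcript", utr5[1], utr3[2]),
      row("exon", utr5[1], cds1[2], extra = " exon_number \"1\";"),
      row("5UTR", utr5[1], utr5[2]),
      row("start_codon", cds1[1], cds1[1] + 2L, frame = "0"),
      row("CDS", cds1[1], cds1[2], frame = "0"),
      row("CDS", cds2[1], cds2[2], frame = "1"),
      row("stop_codon", cds2[2] - 2L, cds2[2], frame = "0"),
      row("3UTR", utr3[1], utr3[2]))
    at <- at + 2000L
  }
  out
}

gen_pdb <- function(params) {
  n <- pget(params, "n_atoms", 30L)
  res3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  atoms <- c(" N  ", " CA ", " C  ", " O  ", " CB ")
  elements <- c(" N", " C", " C", " O", " C")
  out <- c(
    sprintf("%-80s", "HEADER    SYNTHETIC PROTEIN                       23-SEP-26   0XXX"),
    sprintf("%-80s", "TITLE     BIOSHADE FIXTURE STRUCTURE"),
    sprintf("%-80s", "REMARK   2 RESOLUTION. 1.90 ANGSTROMS.")
  )
  resseq <- 1L
  resname <- sample(res3, 1)
  for (i in seq_len(n)) {
    j <- ((i - 1L) %% 5L) + 1L
    if (j == 1L && i > 1L) {
      resseq <- resseq + 1L
      resname <- sample(res3, 1)
    }
    out <- c(out, sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, atoms[j], " ", resname, "A", resseq, " ",
      stats::runif(1, -30, 30), stats::runif(1, -30, 30),
      stats::runif(1, -30, 30), 1.00, stats::runif(1, 5, 95),
      elements[j]))
  }
  c(out, "END")
}

gen_clustal <- function(params) {
  n_seqs <- pget(params, "n_seqs", 4L)
  len <- pget(params, "aln_length", 60L)
  block <- 60L
  base <- strsplit(rand_aa_seq(len), "")[[1]]
  seqs <- lapply(seq_len(n_seqs), function(i) {
    s <- base
    mut <- stats::runif(len) < 0.15
    s[mut] <- sample(setdiff(aa_codes, c("B", "Z", "X")), sum(mut),
                     replace = TRUE)
    gap <- stats::runif(len) < 0.05
    s[gap] <- "-"
    s
  })
  names(seqs) <- sprintf("seq%02d", seq_len(n_seqs))
  cons <- vapply(seq_len(len), function(p) {
    col <- vapply(seqs, `[[`, "", p)
    if (any(col == "-")) " "
    else if (length(unique(col)) == 1) "*"
    else if (length(unique(col)) <= 2) ":"
    else "."
  }, character(1))
  out <- c("CLUSTAL W (1.83) multiple sequence alignment", "")
  namew <- max(nchar(names(seqs))) + 6L
  for (s0 in seq(1, len, by = block)) {
    e0 <- min(s0 + block - 1L, len)
    for (nm in names(seqs)) {
      out <- c(out, sprintf("%-*s%s", namew, nm,
                            paste(seqs[[nm]][s0:e0], collapse = "")))
    }
    out <- c(out, sprintf("%-*s%s", namew, "",
                          paste(cons[s0:e0], collapse = "")), "")
  }
  out[-length(out)]
}
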