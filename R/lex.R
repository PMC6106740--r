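#' Lexer state for a stream
#'
#' Lines are lexed independently given a small per-stream state: the
#' format, whether the stream is still in its header section (SAM/VCF),
#' the sniffed FASTA alphabet, and the position within a multi-line record
#' (the FASTQ 4-line cycle, the CLUSTAL block). This keeps memory O(1) per
#' stream, which the pipe use-case requires.
#'
#' @param format A format id (see [format_ids()]), not `"PLAIN"`.
#' @return An object of class `shade_lex_state`.
#' @examples
#' lex_state("SAM")
#' @export
lex_state <- function(format) {
  format <- match.arg(toupper(format), setdiff(format_ids(), "PLAIN"))
  structure(
    list(format = format, in_header = TRUE,
         fasta_alphabet = "undetermined", record_phase = 0L),
    class = "shade_lex_state"
  )
}

#' @export
print.shade_lex_state <- function(x, ...) {
  cat(sprintf("<shade_lex_state %s header=%s alphabet=%s phase=%d>\n",
              x$format, x$in_header, x$fasta_alphabet, x$record_phase))
  invisible(x)
}

#' Tokenize one line
#'
#' Splits a line of the state's format into classified byte spans. Tokens
#' are 0-based `[start, end)` byte offsets into the raw line, sorted and
#' non-overlapping; bytes not covered by any token render unstyled. The
#' lexer never fails on malformed content — unparseable spans come back
#' with class `"unknown"` — because a viewer must not crash on dirty data.
#' A trailing carriage return is never part of a token.
#'
#' @param state A [lex_state()].
#' @param line A single line (no trailing newline).
#' @return A list with elements `tokens` (a tibble with columns `start`,
#'   `end`, `class`, plus an attribute `line_class` naming a whole-line
#'   background class where one applies) and `state` (the updated state).
#' @examples
#' st <- lex_state("SAM")
#' lex_line(st, "@SQ\tSN:chr1\tLN:248956422")$tokens
#' @export
lex_line <- function(state, line) {
  stopifnot(inherits(state, "shade_lex_state"),
            is.character(line), length(line) == 1)
  res <- lex_line_impl(state, line)
  tok <- tibble::tibble(start = res$s, end = res$e, class = res$k)
  attr(tok, "line_class") <- res$line_class
  list(tokens = tok, state = res$state)
}

# ---- internal engine ----------------------------------------------------

# Fast path used by the streaming renderer: returns plain vectors.
# Works in character coordinates, then remaps to byte offsets when the two
# differ, so tokens never split a multi-byte character.
lex_line_impl <- function(state, line) {
  nb <- nchar(line, type = "bytes")
  if (is.na(nchar(line, type = "chars", allowNA = TRUE)) || !validUTF8(line)) {
    return(list(s = 0L, e = nb, k = "unknown", line_class = NULL,
                state = state))
  }
  nc <- nchar(line)
  content <- line
  if (nc > 0 && substr(line, nc, nc) == "\r") {
    content <- substr(line, 1L, nc - 1L)
  }
  res <- switch(state$format,
    SAM = lex_sam(state, content),
    VCF = lex_vcf(state, content),
    BED = lex_bed(state, content),
    GTF = lex_gtf(state, content),
    PDB = lex_pdb(state, content),
    FASTA = lex_fasta(state, content),
    FASTQ = lex_fastq(state, content),
    CLUSTAL = lex_clustal(state, content),
    stop("cannot lex format ", state$format, call. = FALSE)
  )
  s <- res$s; e <- res$e; k <- res$k
  if (length(s) > 0) {
    keep <- e > s  # blank lines can produce zero-width spans; drop them
    if (!all(keep)) {
      s <- s[keep]; e <- e[keep]; k <- k[keep]
    }
  }
  if (length(s) > 1) {
    o <- order(s)
    s <- s[o]; e <- e[o]; k <- k[o]
  }
  if (nb != nc && length(s) > 0) {
    # byte offset of each character boundary
    widths <- nchar(strsplit(content, "", fixed = TRUE)[[1]], type = "bytes")
    bounds <- cumsum(c(0L, widths))
    s <- bounds[s + 1L]
    e <- bounds[e + 1L]
  }
  list(s = as.integer(s), e = as.integer(e), k = as.character(k),
       line_class = res$line_class, state = res$state)
}

toks <- function(s = integer(0), e = integer(0), k = character(0),
                 line_class = NULL, state) {
  list(s = s, e = e, k = k, line_class = line_class, state = state)
}

# tab fields with their 0-based [start, end) character spans
split_fields <- function(x) {
  f <- strsplit(x, "\t", fixed = TRUE)[[1]]
  if (length(f) == 0) f <- ""
  n <- nchar(f)
  s <- cumsum(c(0L, n + 1L))[seq_along(f)]
  list(f = f, s = s, e = s + n)
}

# ---- per-character class tables (indexed by code point + 1) -------------

nt_class_table <- local({
  tab <- rep(NA_character_, 128)
  for (code in iupac_codes) {
    cls <- paste0("nucleotide.", code)
    tab[utf8ToInt(code) + 1L] <- cls
    tab[utf8ToInt(tolower(code)) + 1L] <- cls
  }
  tab
})

aa_class_table <- local({
  tab <- rep(NA_character_, 128)
  for (res in aa_codes) {
    cls <- paste0("aminoacid.", res)
    tab[utf8ToInt(res) + 1L] <- cls
    tab[utf8ToInt(tolower(res)) + 1L] <- cls
  }
  tab
})

# PHRED+33 base-quality characters: score/40 capped, then binned
phred_class_table <- local({
  tab <- rep(NA_character_, 128)
  for (cp in 33:126) {
    bin <- min(floor(min((cp - 33) / 40, 1) * n_quality_bins),
               n_quality_bins - 1)
    tab[cp + 1L] <- paste0("quality.", bin)
  }
  tab
})

gap_codes <- utf8ToInt("-.* ")

# Per-character tokens for a span of sequence/quality text.
# `table` maps code points to classes; `gaps` lists code points to leave
# unstyled; everything unmapped becomes class "unknown".
char_tokens <- function(text, at, table, gaps = integer(0),
                        dot_eq_to = NULL) {
  cp <- utf8ToInt(text)
  n <- length(cp)
  if (n == 0) return(NULL)
  cls <- rep(NA_character_, n)
  ok <- cp < 128
  cls[ok] <- table[cp[ok] + 1L]
  if (!is.null(dot_eq_to)) {
    cls[cp == 61L | cp == 46L] <- dot_eq_to  # '=' and '.'
  }
  drop <- cp %in% gaps & is.na(cls)
  cls[is.na(cls) & !drop] <- "unknown"
  keep <- which(!drop)
  if (length(keep) == 0) return(NULL)
  list(s = at + keep - 1L, e = at + keep, k = cls[keep])
}

# quality-gradient class for a numeric score string under a divisor
score_bin_class <- function(text, divisor) {
  v <- suppressWarnings(as.numeric(text))
  if (is.na(v) || v < 0) return(NA_character_)
  paste0("quality.", min(floor(min(v / divisor, 1) * n_quality_bins),
                         n_quality_bins - 1))
}

# small builder: chunks of token vectors concatenated once
cat_chunks <- function(chunks, line_class = NULL, state) {
  chunks <- Filter(Negate(is.null), chunks)
  if (length(chunks) == 0) return(toks(state = state, line_class = line_class))
  toks(
    s = unlist(lapply(chunks, `[[`, "s"), use.names = FALSE),
    e = unlist(lapply(chunks, `[[`, "e"), use.names = FALSE),
    k = unlist(lapply(chunks, `[[`, "k"), use.names = FALSE),
    line_class = line_class, state = state
  )
}

tk <- function(s, e, k) if (e > s) list(s = s, e = e, k = k) else NULL

# ---- SAM ----------------------------------------------------------------

sam_header_tags <- c("@HD", "@SQ", "@RG", "@PG", "@CO")

lex_sam <- function(state, x) {
  if (state$in_header && startsWith(x, "@")) {
    return(lex_sam_header(state, x))
  }
  state$in_header <- FALSE
  sp <- split_fields(x)
  f <- sp$f; s <- sp$s; e <- sp$e
  if (length(f) < 11) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  ch <- vector("list", length(f) + 4L)
  ch[[1]] <- tk(s[1], e[1], "read-name")
  ch[[2]] <- tk(s[2], e[2],
                if (grepl("^[0-9]+$", f[2])) "flag" else "unknown")
  ch[[3]] <- tk(s[3], e[3], "coordinate")
  ch[[4]] <- tk(s[4], e[4],
                if (grepl("^[0-9]+$", f[4])) "coordinate" else "unknown")
  mq <- if (grepl("^[0-9]+$", f[5])) score_bin_class(f[5], 60) else NA
  ch[[5]] <- tk(s[5], e[5], if (is.na(mq)) "unknown" else mq)
  ch[[6]] <- sam_cigar_tokens(f[6], s[6])
  ch[[7]] <- tk(s[7], e[7], "coordinate")
  ch[[8]] <- tk(s[8], e[8],
                if (grepl("^[0-9]+$", f[8])) "coordinate" else "unknown")
  # field 9 (TLEN) carries no class
  if (f[10] != "*") {
    ch[[10]] <- char_tokens(f[10], s[10], nt_class_table,
                            dot_eq_to = "nucleotide.N")
  }
  if (f[11] != "*") {
    ch[[11]] <- char_tokens(f[11], s[11], phred_class_table)
  }
  if (length(f) > 11) {
    for (i in 12:length(f)) {
      ch[[i + 3L]] <- sam_optional_field(f[i], s[i], e[i])
    }
  }
  cat_chunks(ch, state = state)
}

lex_sam_header <- function(state, x) {
  sp <- split_fields(x)
  f <- sp$f; s <- sp$s; e <- sp$e
  if (!f[1] %in% sam_header_tags) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  ch <- list(tk(s[1], e[1], "record-type"))
  if (f[1] == "@CO") {
    ch[[2]] <- tk(min(4L, nchar(x)), nchar(x), "comment")
    return(cat_chunks(ch, state = state))
  }
  if (length(f) > 1) {
    for (i in 2:length(f)) {
      if (grepl("^[A-Za-z][A-Za-z0-9]:", f[i])) {
        val_cls <- if (f[1] == "@RG" && startsWith(f[i], "SM:"))
          "sample-info" else "meta-value"
        ch[[length(ch) + 1]] <- tk(s[i], s[i] + 2L, "meta-key")
        ch[[length(ch) + 1]] <- tk(s[i] + 3L, e[i], val_cls)
      } else {
        ch[[length(ch) + 1]] <- tk(s[i], e[i], "unknown")
      }
    }
  }
  cat_chunks(ch, state = state)
}

sam_cigar_tokens <- function(cigar, at) {
  if (cigar == "*") return(NULL)
  p <- parse_cigar_impl(cigar)
  if (!is.null(p$error_at)) {
    return(list(s = at, e = at + nchar(cigar), k = "unknown"))
  }
  if (length(p$op) == 0) return(NULL)
  list(s = at + p$spans_start, e = at + p$spans_end,
       k = unname(cigar_class_of_op[p$op]))
}

sam_optional_field <- function(field, s, e) {
  if (grepl("^[A-Za-z][A-Za-z0-9]:[AifZHBij]:", field)) {
    ch <- list(tk(s, s + 4L, "meta-key"))
    if (e > s + 5L) ch[[2]] <- tk(s + 5L, e, "meta-value")
    cat_chunks(ch, state = NULL)[c("s", "e", "k")]
  } else {
    list(s = s, e = e, k = "unknown")
  }
}

# ---- VCF ----------------------------------------------------------------

lex_vcf <- function(state, x) {
  if (state$in_header && startsWith(x, "##")) {
    eq <- regexpr("=", x, fixed = TRUE)
    n <- nchar(x)
    if (eq > 0) {
      return(cat_chunks(list(tk(0L, eq - 1L, "meta-key"),
                             tk(eq, n, "meta-value")), state = state))
    }
    return(toks(0L, n, "meta-key", state = state))
  }
  if (state$in_header && startsWith(x, "#CHROM")) {
    return(toks(0L, nchar(x), "record-type", state = state))
  }
  state$in_header <- FALSE
  sp <- split_fields(x)
  f <- sp$f; s <- sp$s; e <- sp$e
  if (length(f) < 8) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  ch <- vector("list", length(f) + 2L)
  ch[[1]] <- tk(s[1], e[1], "coordinate")
  ch[[2]] <- tk(s[2], e[2],
                if (grepl("^[0-9]+$", f[2])) "coordinate" else "unknown")
  # field 3 (ID) and field 7 (FILTER) carry no class
  ch[[4]] <- vcf_allele_tokens(f[4], s[4])
  ch[[5]] <- vcf_allele_tokens(f[5], s[5])
  if (f[6] != ".") {
    qb <- score_bin_class(f[6], 100)
    ch[[6]] <- tk(s[6], e[6], if (is.na(qb)) "unknown" else qb)
  }
  if (f[8] != ".") ch[[8]] <- vcf_info_tokens(f[8], s[8])
  if (length(f) >= 9) {
    for (i in 9:length(f)) {
      ch[[i + 2L]] <- tk(s[i], e[i], "sample-info")
    }
  }
  cat_chunks(ch, state = state)
}

vcf_allele_tokens <- function(field, at) {
  if (field %in% c(".", "*")) return(NULL)
  if (grepl("^[A-Za-z,.*]+$", field)) {
    char_tokens(field, at, nt_class_table, gaps = utf8ToInt(",.*"))
  } else {
    list(s = at, e = at + nchar(field), k = "unknown")
  }
}

vcf_info_tokens <- function(field, at) {
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  n <- nchar(parts)
  ps <- cumsum(c(0L, n + 1L))[seq_along(parts)]
  ch <- vector("list", 2L * length(parts))
  for (i in seq_along(parts)) {
    eq <- regexpr("=", parts[i], fixed = TRUE)
    if (eq > 0) {
      ch[[2 * i - 1]] <- tk(at + ps[i], at + ps[i] + eq - 1L, "meta-key")
      ch[[2 * i]] <- tk(at + ps[i] + eq, at + ps[i] + n[i], "meta-value")
    } else if (n[i] > 0) {
      ch[[2 * i - 1]] <- tk(at + ps[i], at + ps[i] + n[i], "meta-key")
    }
  }
  cat_chunks(ch, state = NULL)[c("s", "e", "k")]
}

# ---- BED ----------------------------------------------------------------

lex_bed <- function(state, x) {
  if (startsWith(x, "#") || startsWith(x, "track") ||
      startsWith(x, "browser")) {
    return(toks(0L, nchar(x), "comment", state = state))
  }
  sp <- split_fields(x)
  f <- sp$f; s <- sp$s; e <- sp$e
  if (length(f) < 3) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  ch <- vector("list", 6L)
  ch[[1]] <- tk(s[1], e[1], "coordinate")
  for (i in 2:3) {
    ch[[i]] <- tk(s[i], e[i],
                  if (grepl("^[0-9]+$", f[i])) "coordinate" else "unknown")
  }
  if (length(f) >= 4) ch[[4]] <- tk(s[4], e[4], "read-name")
  if (length(f) >= 5 && f[5] != ".") {
    qb <- score_bin_class(f[5], 1000)
    ch[[5]] <- tk(s[5], e[5], if (is.na(qb)) "unknown" else qb)
  }
  if (length(f) >= 6 && f[6] != ".") {
    ch[[6]] <- tk(s[6], e[6],
                  if (f[6] %in% c("+", "-")) "strand" else "unknown")
  }
  cat_chunks(ch, state = state)
}

# ---- GTF ----------------------------------------------------------------

gtf_feature_class <- function(feature) {
  switch(tolower(feature),
    cds = "feature.cds",
    utr = , "5utr" = , "3utr" = , five_prime_utr = ,
    three_prime_utr = "feature.utr",
    start_codon = "feature.start-codon",
    stop_codon = "feature.stop-codon",
    "feature.other"
  )
}

lex_gtf <- function(state, x) {
  if (startsWith(x, "#")) {
    return(toks(0L, nchar(x), "comment", state = state))
  }
  sp <- split_fields(x)
  f <- sp$f; s <- sp$s; e <- sp$e
  if (length(f) < 9) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  feat_cls <- gtf_feature_class(f[3])
  line_class <- if (feat_cls != "feature.other") feat_cls else NULL
  ch <- vector("list", 8L)
  ch[[1]] <- tk(s[1], e[1], "coordinate")
  ch[[2]] <- tk(s[3], e[3], feat_cls)
  for (i in 4:5) {
    ch[[i]] <- tk(s[i], e[i],
                  if (grepl("^[0-9]+$", f[i])) "coordinate" else "unknown")
  }
  if (f[6] != ".") {
    qb <- score_bin_class(f[6], 1000)
    ch[[6]] <- tk(s[6], e[6], if (is.na(qb)) "unknown" else qb)
  }
  if (f[7] != ".") {
    ch[[7]] <- tk(s[7], e[7],
                  if (f[7] %in% c("+", "-")) "strand" else "unknown")
  }
  ch[[8]] <- gtf_attribute_tokens(f[9], s[9])
  cat_chunks(ch, line_class = line_class, state = state)
}

gtf_attribute_tokens <- function(field, at) {
  m <- gregexpr("([A-Za-z_][A-Za-z0-9_]*)[ ]+(\"[^\"]*\"|[^;\"]+)",
                field, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    if (!nzchar(field)) return(NULL)
    return(list(s = at, e = at + nchar(field), k = "unknown"))
  }
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  n <- nrow(cs)
  list(
    s = at + c(cs[, 1], cs[, 2]) - 1L,
    e = at + c(cs[, 1] + cl[, 1], cs[, 2] + cl[, 2]) - 1L,
    k = rep(c("meta-key", "meta-value"), each = n)
  )
}

# ---- PDB ----------------------------------------------------------------

# 1-based inclusive column span, trimmed of surrounding spaces
pdb_col_token <- function(x, c1, c2, cls) {
  n <- nchar(x)
  if (c1 > n) return(NULL)
  c2 <- min(c2, n)
  piece <- substr(x, c1, c2)
  lead <- regexpr("[^ ]", piece)
  if (lead < 0) return(NULL)
  trail <- nchar(sub(" +$", "", piece))
  tk(c1 + lead - 2L, c1 + trail - 1L, cls)
}

lex_pdb <- function(state, x) {
  rec <- toupper(sub(" .*", "", substr(x, 1, 6)))
  if (!grepl("^[A-Z0-9]+$", rec)) {
    return(toks(0L, nchar(x), "unknown", state = state))
  }
  ch <- list(pdb_col_token(x, 1, 6, "record-type"))
  if (rec %in% c("ATOM", "HETATM")) {
    ch[[2]] <- pdb_col_token(x, 13, 16, "meta-key")    # atom name
    ch[[3]] <- pdb_col_token(x, 18, 20, "meta-value")  # residue name
    ch[[4]] <- pdb_col_token(x, 22, 22, "meta-key")    # chain
    ch[[5]] <- pdb_col_token(x, 23, 26, "meta-value")  # residue seq number
    ch[[6]] <- pdb_col_token(x, 31, 38, "meta-value")  # x
    ch[[7]] <- pdb_col_token(x, 39, 46, "meta-value")  # y
    ch[[8]] <- pdb_col_token(x, 47, 54, "meta-value")  # z
    btxt <- trimws(substr(x, 61, 66))
    if (nzchar(btxt)) {
      qb <- score_bin_class(btxt, 100)
      ch[[9]] <- pdb_col_token(x, 61, 66, if (is.na(qb)) "unknown" else qb)
    }
    ch[[10]] <- pdb_col_token(x, 77, 78, "meta-key")   # element
  } else if (rec == "REMARK") {
    ch[[2]] <- pdb_col_token(x, 12, nchar(x), "comment")
  }
  cat_chunks(ch, state = state)
}

# ---- FASTA --------------------------------------------------------------

lex_fasta <- function(state, x) {
  n <- nchar(x)
  if (n == 0) return(toks(state = state))
  if (startsWith(x, ">")) {
    return(toks(0L, n, "read-name", state = state))
  }
  if (startsWith(x, ";")) {
    return(toks(0L, n, "comment", state = state))
  }
  if (state$fasta_alphabet == "undetermined") {
    state$fasta_alphabet <- tryCatch(sniff_alphabet(x),
                                     error = function(e) "undetermined")
    if (state$fasta_alphabet == "undetermined") {
      return(toks(state = state))
    }
  }
  tab <- if (state$fasta_alphabet == "nucleotide") nt_class_table
         else aa_class_table
  cat_chunks(list(char_tokens(x, 0L, tab, gaps = gap_codes)), state = state)
}

# ---- FASTQ --------------------------------------------------------------

lex_fastq <- function(state, x) {
  n <- nchar(x)
  phase <- state$record_phase
  advance <- function(st) { st$record_phase <- (phase + 1L) %% 4L; st }
  if (phase == 0L) {
    if (!startsWith(x, "@")) {
      return(toks(0L, n, "unknown", state = state))  # resynchronise on '@'
    }
    return(toks(0L, n, "read-name", state = advance(state)))
  }
  if (phase == 1L) {
    return(cat_chunks(
      list(char_tokens(x, 0L, nt_class_table, dot_eq_to = "nucleotide.N")),
      state = advance(state)
    ))
  }
  if (phase == 2L) {
    cls <- if (startsWith(x, "+")) "comment" else "unknown"
    return(toks(0L, n, cls, state = advance(state)))
  }
  cat_chunks(list(char_tokens(x, 0L, phred_class_table)),
             state = advance(state))
}

# ---- CLUSTAL ------------------------------------------------------------

lex_clustal <- function(state, x) {
  n <- nchar(x)
  if (state$in_header && grepl("^CLUSTAL", x)) {
    state$in_header <- FALSE
    return(toks(0L, n, "record-type", state = state))
  }
  if (n == 0 || !nzchar(trimws(x))) return(toks(state = state))
  if (grepl("^[ *:.]+$", x)) {
    lead <- regexpr("[^ ]", x)
    if (lead < 0) return(toks(state = state))
    trail <- nchar(sub(" +$", "", x))
    return(toks(lead - 1L, trail, "comment", state = state))
  }
  state$in_header <- FALSE
  m <- regexpr("^(\\S+)([ \t]+)(\\S+)", x, perl = TRUE)
  if (m < 0) return(toks(0L, n, "unknown", state = state))
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  ch <- list(tk(cs[1] - 1L, cs[1] + cl[1] - 1L, "read-name"),
             char_tokens(substr(x, cs[3], cs[3] + cl[3] - 1L),
                         cs[3] - 1L, aa_class_table, gaps = gap_codes))
  # optional trailing cumulative residue count
  m2 <- regexpr("[ \t]([0-9]+)[ ]*$", x, perl = TRUE)
  if (m2 > 0) {
    c2 <- attr(m2, "capture.start")
    l2 <- attr(m2, "capture.length")
    if (c2[1] - 1L >= cs[3] + cl[3]) {
      ch[[3]] <- tk(c2[1] - 1L, c2[1] + l2[1] - 1L, "meta-value")
    }
  }
  cat_chunks(ch, state = state)
}
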