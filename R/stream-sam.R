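# Vectorized renderer for chunks of SAM body lines. Produces byte-identical
# output to the generic per-line path for well-formed records, but processes
# a whole chunk with vectorized string operations — the throughput path that
# lets a full alignment stream through a pager without lag. Lines that need
# byte-level care (fewer than 11 fields, non-ASCII, carriage returns) fall
# back to the generic path individually.

phred_bin_table <- local({
  tab <- rep(NA_integer_, 128)
  for (cp in 33:126) {
    tab[cp + 1L] <- min(floor(min((cp - 33) / 40, 1) * n_quality_bins),
                        n_quality_bins - 1L)
  }
  tab
})

# IUPAC run patterns for gsub-based sequence colouring. The M/m pattern must
# run first: inserted escapes end in a literal "m", which no later pattern
# may match ('=' and '.' share the N class so adjacent runs coalesce).
seq_run_patterns <- local({
  codes <- c("M", setdiff(setdiff(iupac_codes, "N"), "M"))
  pats <- vapply(codes, function(cd) paste0("[", cd, tolower(cd), "]+"),
                 character(1))
  stats::setNames(c(unname(pats), "[Nn=.]+"),
                  paste0("nucleotide.", c(codes, "N")))
})

cigar_ops_vec <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
cigar_run_patterns <- sprintf("(?:[0-9]+%s)+", cigar_ops_vec)

cigar_valid_re <- "^([0-9]*[1-9][0-9]*[MIDNSHP=X])+$"

render_sam_chunk <- function(lines, theme) {
  n <- length(lines)
  out <- character(n)
  slow <- nchar(lines, type = "bytes") != nchar(lines, allowNA = TRUE) |
    !validUTF8(lines) | endsWith(lines, "\r")
  slow[is.na(slow)] <- TRUE
  sp <- strsplit(lines, "\t", fixed = TRUE)
  slow <- slow | lengths(sp) < 11
  if (any(slow)) {
    st <- lex_state("SAM"); st$in_header <- FALSE
    for (i in which(slow)) {
      r <- lex_line_impl(st, lines[i])
      out[i] <- render_ansi_impl(lines[i], r$s, r$e, r$k, theme,
                                 r$line_class)
    }
    if (all(slow)) return(out)
    sp <- sp[!slow]
  }
  esc <- theme$escapes
  R <- "\033[0m"
  wrap <- function(x, cls) {
    e <- esc[[cls]]
    if (e == "") x else paste0(e, x, R)
  }
  qesc <- unname(esc[paste0("quality.", 0:5)])
  fld <- function(i) vapply(sp, `[[`, "", i)

  qname <- wrap(fld(1), "read-name")
  f2 <- fld(2)
  flag <- ifelse(grepl("^[0-9]+$", f2), wrap(f2, "flag"), f2)
  rname <- wrap(fld(3), "coordinate")
  f4 <- fld(4)
  pos <- ifelse(grepl("^[0-9]+$", f4), wrap(f4, "coordinate"), f4)
  f5 <- fld(5)
  mapq <- f5
  mq <- suppressWarnings(as.numeric(f5))
  ok <- grepl("^[0-9]+$", f5) & !is.na(mq)
  bin <- pmin(floor(pmin(mq[ok] / 60, 1) * n_quality_bins),
              n_quality_bins - 1L)
  mapq[ok] <- ifelse(nzchar(qesc[bin + 1L]),
                     paste0(qesc[bin + 1L], f5[ok], R), f5[ok])
  f6 <- fld(6)
  cigar <- f6
  cig_ok <- f6 != "*" & grepl(cigar_valid_re, f6)
  if (any(cig_ok)) {
    x <- f6[cig_ok]
    for (j in seq_along(cigar_ops_vec)) {
      e <- esc[[cigar_class_of_op[[cigar_ops_vec[j]]]]]
      if (e != "") x <- sub_runs(cigar_run_patterns[j], e, x)
    }
    cigar[cig_ok] <- paste0(x, R)
  }
  rnext <- wrap(fld(7), "coordinate")
  f8 <- fld(8)
  pnext <- ifelse(grepl("^[0-9]+$", f8), wrap(f8, "coordinate"), f8)
  tlen <- fld(9)
  f10 <- fld(10)
  seq_ <- f10
  seq_ok <- f10 != "*"
  if (any(seq_ok)) {
    x <- f10[seq_ok]
    for (cls in names(seq_run_patterns)) {
      e <- esc[[cls]]
      if (e != "") {
        x <- sub_runs(seq_run_patterns[[cls]], e, x)
      }
    }
    styled_end <- grepl("[ACGTURYSWKMBDHVNacgturyswkmbdhvn=.]$", f10[seq_ok])
    seq_[seq_ok] <- paste0(x, ifelse(styled_end, R, ""))
  }
  qual <- render_qual_vec(fld(11), qesc, R)
  base <- paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
                seq_, qual, sep = "\t")

  counts <- lengths(sp) - 11L
  if (any(counts > 0)) {
    opt <- unlist(lapply(sp, function(f) {
      if (length(f) > 11L) f[12:length(f)]
    }), use.names = FALSE)
    valid <- grepl("^[A-Za-z][A-Za-z0-9]:[AifZHBij]:", opt)
    key <- substr(opt, 1L, 4L)
    val <- substring(opt, 6L)
    rendered <- opt
    rendered[valid] <- paste0(wrap(key[valid], "meta-key"), ":",
                              ifelse(nzchar(val[valid]),
                                     wrap(val[valid], "meta-value"), ""))
    id <- factor(rep.int(seq_along(sp), counts), levels = seq_along(sp))
    opt_line <- vapply(split(rendered, id), paste, character(1),
                       collapse = "\t")
    base <- ifelse(counts > 0, paste0(base, "\t", opt_line), base)
  }
  out[if (any(slow)) which(!slow) else seq_len(n)] <- base
  out
}

# prefix every match of `pattern` with `escape`; content unchanged
sub_runs <- function(pattern, escape, x) {
  gsub(paste0("(", pattern, ")"), paste0(escape, "\\1"), x, perl = TRUE)
}

# per-character quality gradient with run coalescing, vectorized over the
# whole chunk: runs of equal bin share one escape, unstyled characters
# after a styled run are preceded by a reset, and a trailing reset is
# appended when the final run is styled (the next byte is a tab or EOL).
render_qual_vec <- function(fq, qesc, R) {
  out <- fq
  todo <- which(fq != "*" & nzchar(fq))
  if (length(todo) == 0) return(out)
  v <- fq[todo]
  lens <- nchar(v)
  big <- paste(v, collapse = "")
  cp <- utf8ToInt(big)
  bin <- rep(6L, length(cp))
  small <- cp < 128L
  b <- phred_bin_table[cp[small] + 1L]
  b[is.na(b)] <- 6L
  bin[small] <- b
  id <- rep.int(seq_along(v), lens)
  r <- rle(id * 8L + bin)
  run_id <- r$values %/% 8L
  run_bin <- r$values %% 8L
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  txt <- substring(big, starts, ends)
  nr <- length(run_id)
  same_line <- c(FALSE, run_id[-nr] == run_id[-1])
  prev_styled <- c(FALSE, run_bin[-nr] < 6L) & same_line
  piece <- paste0(
    ifelse(run_bin < 6L, qesc[pmin(run_bin, 5L) + 1L],
           ifelse(prev_styled, R, "")),
    txt
  )
  line_out <- vapply(split(piece, factor(run_id, levels = seq_along(v))),
                     paste, character(1), collapse = "")
  last_styled <- run_bin[!duplicated(run_id, fromLast = TRUE)] < 6L
  out[todo] <- paste0(line_out, ifelse(last_styled, R, ""))
  out
}
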