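#' Re-map a theme's amino-acid classes to a published scheme
#'
#' Returns a copy of `theme` whose `aminoacid.*` entries are taken from one
#' of the published schemes (see [amino_acid_color()]); residues a scheme
#' leaves out render unstyled.
#'
#' @param theme A [shade_theme()].
#' @param scheme `"clustal"`, `"taylor"`, `"zappo"` or `"hydrophobicity"`.
#' @return A [shade_theme()].
#' @examples
#' th <- apply_aa_scheme(shade_theme("default"), "zappo")
#' @export
apply_aa_scheme <- function(theme, scheme) {
  stopifnot(inherits(theme, "shade_theme"))
  for (res in aa_codes) {
    theme$classes[[paste0("aminoacid.", res)]] <-
      amino_acid_color(res, scheme)
  }
  theme$escapes <- build_escape_table(theme)
  theme
}

#' Highlight a character vector of lines
#'
#' Lexes and renders each line in order, threading the per-stream state
#' (header/body transitions, FASTQ phase, FASTA alphabet) through the
#' vector. `format = "PLAIN"` returns the lines unchanged.
#'
#' @param lines Character vector of raw lines.
#' @param format A format id (see [format_ids()]); `NULL` to sniff from
#'   the lines themselves.
#' @param theme A [shade_theme()].
#' @param aa_scheme Optional amino-acid scheme name applied to the theme.
#' @param html Render HTML fragments instead of ANSI text.
#' @return A character vector of rendered lines, same length as `lines`.
#' @examples
#' highlight_lines(c(">read1", "ACGT"), "FASTA")
#' @export
highlight_lines <- function(lines, format = NULL,
                            theme = shade_theme("default"),
                            aa_scheme = NULL, html = FALSE) {
  stopifnot(is.character(lines))
  if (is.null(format)) format <- detect_format(NULL, utils::head(lines, 50))
  format <- match.arg(toupper(format), format_ids())
  if (format == "PLAIN") return(lines)
  if (!is.null(aa_scheme)) theme <- apply_aa_scheme(theme, aa_scheme)
  state <- lex_state(format)
  out <- character(length(lines))
  for (i in seq_along(lines)) {
    res <- lex_line_impl(state, lines[i])
    state <- res$state
    out[i] <- if (html) {
      render_html(lines[i], list(s = res$s, e = res$e, k = res$k), theme,
                  line_class = res$line_class)
    } else {
      render_ansi_impl(lines[i], res$s, res$e, res$k, theme, res$line_class)
    }
  }
  out
}

#' Stream-highlight a file or connection
#'
#' Reads lines in fixed-size chunks, lexes and renders them, and writes the
#' result to an output connection. Memory use is bounded by the chunk size,
#' independent of stream length, so arbitrarily large files can be piped
#' through. Gzip-compressed input is handled transparently when `input` is
#' a path.
#'
#' @param input A file path, or a readable connection.
#' @param output A writable connection (default `stdout()`).
#' @param format A format id, or `NULL` to detect from the file name and
#'   leading content. `"PLAIN"` copies lines through unhighlighted.
#' @param theme A [shade_theme()].
#' @param aa_scheme Optional amino-acid scheme name.
#' @param html Render HTML fragments instead of ANSI text.
#' @param chunk_size Lines per read.
#' @param path_hint File name used for extension-based detection when
#'   `input` is a connection.
#' @return Invisibly, the number of lines processed.
#' @examples
#' out <- textConnection(NULL, "w", local = TRUE)
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT"), f)
#' shade_stream(f, output = out)
#' close(out)
#' @export
shade_stream <- function(input, output = stdout(), format = NULL,
                         theme = shade_theme("default"), aa_scheme = NULL,
                         html = FALSE, chunk_size = 4000L,
                         path_hint = NULL) {
  if (is.character(input)) {
    path_hint <- input
    con <- gzfile(input, "r")  # reads plain files transparently too
    on.exit(close(con), add = TRUE)
  } else {
    con <- input
  }
  if (!is.null(aa_scheme)) theme <- apply_aa_scheme(theme, aa_scheme)
  first <- readLines(con, n = chunk_size, warn = FALSE)
  if (is.null(format)) {
    format <- detect_format(path_hint, utils::head(first, 50))
  }
  format <- match.arg(toupper(format), format_ids())
  n_total <- 0L
  if (format == "PLAIN") {
    chunk <- first
    while (length(chunk) > 0) {
      writeLines(chunk, output)
      n_total <- n_total + length(chunk)
      chunk <- readLines(con, n = chunk_size, warn = FALSE)
    }
    return(invisible(n_total))
  }
  state <- lex_state(format)
  chunk <- first
  while (length(chunk) > 0) {
    if (format == "SAM" && !html) {
      out <- character(length(chunk))
      # header prefix (if any) through the stateful path, body vectorized
      n_hdr <- 0L
      if (state$in_header) {
        hdr <- cumprod(startsWith(chunk, "@")) == 1
        n_hdr <- sum(hdr)
        for (i in seq_len(n_hdr)) {
          res <- lex_line_impl(state, chunk[i])
          state <- res$state
          out[i] <- render_ansi_impl(chunk[i], res$s, res$e, res$k, theme,
                                     res$line_class)
        }
        if (n_hdr < length(chunk)) state$in_header <- FALSE
      }
      if (n_hdr < length(chunk)) {
        body <- (n_hdr + 1L):length(chunk)
        out[body] <- render_sam_chunk(chunk[body], theme)
      }
    } else {
      out <- character(length(chunk))
      for (i in seq_along(chunk)) {
        res <- lex_line_impl(state, chunk[i])
        state <- res$state
        out[i] <- if (html) {
          render_html(chunk[i], list(s = res$s, e = res$e, k = res$k), theme,
                      line_class = res$line_class)
        } else {
          render_ansi_impl(chunk[i], res$s, res$e, res$k, theme,
                           res$line_class)
        }
      }
    }
    writeLines(out, output)
    n_total <- n_total + length(chunk)
    chunk <- readLines(con, n = chunk_size, warn = FALSE)
  }
  invisible(n_total)
}
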