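#' Render a tokenized line as ANSI-coloured text
#'
#' Inserts SGR escape sequences (`38;5;<n>` foreground, `48;5;<n>`
#' background, `1` bold, `0` reset) at token boundaries. Content bytes are
#' emitted unchanged and in order, so stripping the escapes always recovers
#' the input line exactly. Classes a theme maps to "no styling" produce no
#' escapes; a reset is emitted wherever styling would otherwise bleed past
#' a token, and at end-of-line so pagers never carry colour across lines.
#' Adjacent tokens of the same class are coalesced into one escape region.
#'
#' @param line The raw line (no newline).
#' @param tokens A tibble (or list) with `start`, `end`, `class` as
#'   produced by [lex_line()]; 0-based byte spans, sorted, non-overlapping.
#' @param theme A [shade_theme()].
#' @param line_class Optional style class whose background colour is
#'   applied across the whole line (defaults to the tokens'
#'   `line_class` attribute).
#' @return The line with escape sequences inserted.
#' @examples
#' th <- shade_theme("default")
#' lx <- lex_line(lex_state("FASTA"), "ACGT")
#' cat(render_ansi("ACGT", lx$tokens, th), "\n")
#' @export
render_ansi <- function(line, tokens, theme,
                        line_class = attr(tokens, "line_class")) {
  stopifnot(inherits(theme, "shade_theme"))
  t <- as_token_vectors(tokens)
  render_ansi_impl(line, t$s, t$e, t$k, theme, line_class)
}

as_token_vectors <- function(tokens) {
  if (is.data.frame(tokens)) {
    list(s = as.integer(tokens$start), e = as.integer(tokens$end),
         k = as.character(tokens$class))
  } else {
    list(s = as.integer(tokens$s), e = as.integer(tokens$e),
         k = as.character(tokens$k))
  }
}

check_tokens <- function(s, e, k, nb) {
  if (length(s) == 0) return(invisible())
  if (anyNA(s) || anyNA(e) || anyNA(k) ||
      any(s < 0L) || any(e <= s) || any(e > nb)) {
    stop("tokens out of bounds for line", call. = FALSE)
  }
  if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
    stop("tokens overlap or are unsorted", call. = FALSE)
  }
  invisible()
}

# substring by byte offsets (0-based starts, exclusive ends)
substr_bytes <- function(line, s0, e0, ascii = NA) {
  if (length(s0) == 0) return(character(0))
  if (is.na(ascii)) {
    nc <- nchar(line, type = "chars", allowNA = TRUE)
    ascii <- !is.na(nc) && nchar(line, type = "bytes") == nc
  }
  if (ascii) return(substring(line, s0 + 1L, e0))
  raw <- charToRaw(line)
  vapply(seq_along(s0), function(i) {
    if (e0[i] <= s0[i]) "" else rawToChar(raw[(s0[i] + 1L):e0[i]])
  }, character(1))
}

# The line is modelled as alternating segments: gap, token, gap, ...
# A styled segment opens with its escape (which begins with a reset, so
# styles never stack); an unstyled non-empty segment after active styling
# is preceded by a reset (or by the line-background filler when a
# line-level background is in force). A final reset closes the line
# whenever styling is still active at end-of-line.
render_ansi_impl <- function(line, s, e, k, theme, line_class = NULL) {
  nb <- nchar(line, type = "bytes")
  check_tokens(s, e, k, nb)
  n <- length(s)
  if (n == 0 && is.null(line_class)) return(line)
  esc <- unname(theme$escapes[k])
  if (anyNA(esc)) {
    stop("unknown style class: ", paste(unique(k[is.na(esc)]), collapse = ", "),
         call. = FALSE)
  }
  # coalesce adjacent same-class tokens
  if (n > 1) {
    join <- k[-1] == k[-n] & s[-1] == e[-n]
    if (any(join)) {
      grp <- cumsum(c(TRUE, !join))
      s <- s[!duplicated(grp)]
      e <- e[cumsum(tabulate(grp))]
      k <- k[!duplicated(grp)]
      esc <- unname(theme$escapes[k])
      n <- length(s)
    }
  }
  plain_fill <- "\033[0m"
  has_bg <- FALSE
  if (!is.null(line_class)) {
    col <- theme$classes[[line_class]]
    if (!is.null(col) && !is.null(col$bg_ansi256)) {
      has_bg <- TRUE
      bg_code <- paste0(";48;5;", col$bg_ansi256)
      plain_fill <- paste0("\033[0", bg_code, "m")
      # token escapes re-assert the line background after their leading
      # reset; a token's own background comes later in the SGR and wins
      styled_tok <- nzchar(esc)
      esc[styled_tok] <- sub("\033[0", paste0("\033[0", bg_code),
                             esc[styled_tok], fixed = TRUE)
    }
  }
  nc <- nchar(line, type = "chars", allowNA = TRUE)
  ascii <- !is.na(nc) && nb == nc
  # interleave: seg 1,3,5,... gaps; seg 2,4,... tokens
  seg_text <- character(2L * n + 1L)
  seg_esc <- character(2L * n + 1L)
  seg_text[2L * seq_len(n + 1L) - 1L] <-
    substr_bytes(line, c(0L, e), c(s, nb), ascii)
  if (n > 0) {
    seg_text[2L * seq_len(n)] <- substr_bytes(line, s, e, ascii)
    seg_esc[2L * seq_len(n)] <- esc
  }
  styled <- nzchar(seg_esc)
  nonempty <- nzchar(seg_text)
  # styling active after each segment: styled -> on, unstyled non-empty ->
  # off (it will have been preceded by a reset), empty -> unchanged
  v <- rep(NA_integer_, length(seg_text))
  v[styled] <- 1L
  v[!styled & nonempty] <- 0L
  known <- !is.na(v)
  vals <- c(if (has_bg) 1L else 0L, v[known])
  active_after <- vals[cumsum(known) + 1L]
  active_before <- c(vals[1], active_after[-length(active_after)])
  filler <- nonempty & !styled & active_before == 1L
  pieces <- paste0(ifelse(filler, plain_fill, ""), seg_esc, seg_text)
  out <- paste(pieces, collapse = "")
  if (has_bg || active_after[length(active_after)] == 1L) {
    out <- paste0(out, "\033[0m")
  }
  out
}

#' Remove SGR escape sequences
#'
#' The inverse of [render_ansi()] styling: deletes every `ESC [ ... m`
#' sequence and returns the remaining bytes unchanged. Idempotent.
#'
#' @param s A character vector.
#' @return `s` without SGR sequences.
#' @examples
#' strip_ansi("\033[38;5;46mA\033[0m")
#' @export
strip_ansi <- function(s) {
  gsub("\033\\[[0-9;]*m", "", s, useBytes = TRUE)
}

#' Render a tokenized line as HTML
#'
#' HTML-escapes the content and wraps each styled token in a `<span>` with
#' inline colour styles; stripping tags and unescaping entities recovers
#' the input line exactly.
#'
#' @inheritParams render_ansi
#' @return An HTML fragment for the line.
#' @examples
#' th <- shade_theme("default")
#' lx <- lex_line(lex_state("FASTA"), "ACGT")
#' render_html("ACGT", lx$tokens, th)
#' @export
render_html <- function(line, tokens, theme,
                        line_class = attr(tokens, "line_class")) {
  stopifnot(inherits(theme, "shade_theme"))
  t <- as_token_vectors(tokens)
  s <- t$s; e <- t$e; k <- t$k
  nb <- nchar(line, type = "bytes")
  check_tokens(s, e, k, nb)
  n <- length(s)
  styles <- vapply(k, function(cls) {
    if (!cls %in% names(theme$classes)) {
      stop("unknown style class: ", cls, call. = FALSE)
    }
    col <- theme$classes[[cls]]
    if (is.null(col)) return("")
    st <- paste0("color:", rgb_to_hex(col$r, col$g, col$b))
    if (!is.null(col$bg)) {
      st <- paste0(st, ";background-color:",
                   rgb_to_hex(col$bg[1], col$bg[2], col$bg[3]))
    }
    if (col$bold) st <- paste0(st, ";font-weight:bold")
    st
  }, character(1))
  nc <- nchar(line, type = "chars", allowNA = TRUE)
  ascii <- !is.na(nc) && nb == nc
  gap_text <- html_escape(substr_bytes(line, c(0L, e), c(s, nb), ascii))
  tok_text <- html_escape(substr_bytes(line, s, e, ascii))
  spans <- ifelse(nzchar(styles),
                  paste0("<span style=\"", styles, "\">", tok_text, "</span>"),
                  tok_text)
  body <- paste(c(rbind(gap_text, c(spans, ""))), collapse = "")
  if (!is.null(line_class)) {
    col <- theme$classes[[line_class]]
    if (!is.null(col) && !is.null(col$bg)) {
      body <- paste0("<span style=\"background-color:",
                     rgb_to_hex(col$bg[1], col$bg[2], col$bg[3]), "\">",
                     body, "</span>")
    }
  }
  body
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE, useBytes = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE, useBytes = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE, useBytes = TRUE)
}

#' Undo HTML rendering (test oracle)
#'
#' Strips tags and unescapes the three entities [render_html()] produces.
#'
#' @param s A character vector of HTML fragments.
#' @return The recovered plain text.
#' @export
strip_html <- function(s) {
  s <- gsub("<[^>]*>", "", s, useBytes = TRUE)
  s <- gsub("&lt;", "<", s, fixed = TRUE, useBytes = TRUE)
  s <- gsub("&gt;", ">", s, fixed = TRUE, useBytes = TRUE)
  gsub("&amp;", "&", s, fixed = TRUE, useBytes = TRUE)
}
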