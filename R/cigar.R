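#' Parse a CIGAR alignment string
#'
#' Decomposes a CIGAR string (run-length description of how a read aligns
#' to the reference, e.g. `"10M1I5M2S"`) into its ordered operations. The
#' placeholder `"*"` (alignment information unavailable) yields zero rows.
#' Operators are the nine defined for SAM: M, I, D, N, S, H, P, `=`, X.
#'
#' @param cigar A single non-empty CIGAR string.
#' @return A tibble with columns `length` (integer >= 1) and `op`
#'   (single-character operator), one row per operation in order.
#' @examples
#' parse_cigar("10M1I5M2S")
#' parse_cigar("*")
#' @export
parse_cigar <- function(cigar) {
  if (!is.character(cigar) || length(cigar) != 1 || !nzchar(cigar)) {
    stop("cigar must be a single non-empty string", call. = FALSE)
  }
  res <- parse_cigar_impl(cigar)
  if (!is.null(res$error_at)) {
    stop(sprintf("malformed CIGAR %s at offset %d", deparse(cigar),
                 res$error_at), call. = FALSE)
  }
  tibble::tibble(length = res$length, op = res$op)
}

# Shared grammar engine. Returns list(length=, op=, spans_start=, spans_end=)
# on success (0-based [start, end) byte spans of each run in the string), or
# list(error_at = <0-based offset of the first offending byte>) on failure.
# Never throws: the lexer needs the failure case as data.
parse_cigar_impl <- function(cigar) {
  if (identical(cigar, "*")) {
    return(list(length = integer(0), op = character(0),
                spans_start = integer(0), spans_end = integer(0)))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(error_at = 0L))
  lens <- attr(m, "match.length")
  # runs must tile the whole string with no gaps
  starts <- as.integer(m)
  ends <- starts + lens - 1L
  expect <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] != expect) return(list(error_at = expect - 1L))
    expect <- ends[i] + 1L
  }
  if (expect != nchar(cigar) + 1L) return(list(error_at = expect - 1L))
  runs <- substring(cigar, starts, ends)
  n <- nchar(runs)
  op <- substring(runs, n, n)
  len <- suppressWarnings(as.integer(substring(runs, 1, n - 1L)))
  if (anyNA(len)) return(list(error_at = starts[which(is.na(len))[1]] - 1L))
  bad <- which(len < 1L)
  if (length(bad) > 0) return(list(error_at = starts[bad[1]] - 1L))
  list(length = len, op = op, spans_start = starts - 1L,
       spans_end = ends)  # ends are 1-based inclusive == 0-based exclusive
}
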