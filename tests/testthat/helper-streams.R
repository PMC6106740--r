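# Shared test helpers: token collection over whole files, fuzz-line
# generators, and an independent ANSI-256 nearest-neighbour oracle.

# lex every line of a file, returning one tibble of tokens with line ids
lex_all <- function(lines, format) {
  st <- lex_state(format)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- lex_line(st, lines[i])
    st <- r$state
    if (nrow(r$tokens) > 0) {
      out[[i]] <- cbind(line = i, r$tokens)
    }
  }
  do.call(rbind, out)
}

# random byte-string line: any byte except NUL, newline and ESC (a raw
# ESC in the *input* would defeat the strip-based round-trip oracle)
fuzz_bytes <- function(max_len = 120) {
  n <- sample.int(max_len, 1)
  rawToChar(as.raw(sample(setdiff(c(1:9, 11:255), 27L), n, replace = TRUE)))
}

# random printable line with tab structure (closer to real field data)
fuzz_fields <- function() {
  nfield <- sample.int(14, 1)
  fields <- vapply(seq_len(nfield), function(i) {
    n <- sample.int(12, 1)
    rawToChar(as.raw(sample(32:126, n, replace = TRUE)))
  }, character(1))
  paste(fields, collapse = "\t")
}

# independent nearest-neighbour oracle over the xterm-256 palette,
# built here from the published cube/gray-ramp definition
oracle_ansi256 <- function(r, g, b) {
  levels <- c(0, 95, 135, 175, 215, 255)
  pal <- matrix(0, nrow = 240, ncol = 3)
  i <- 1
  for (rr in levels) for (gg in levels) for (bb in levels) {
    pal[i, ] <- c(rr, gg, bb); i <- i + 1
  }
  for (k in 0:23) {
    pal[i, ] <- rep(8 + 10 * k, 3); i <- i + 1
  }
  d <- (pal[, 1] - r)^2 + (pal[, 2] - g)^2 + (pal[, 3] - b)^2
  15L + which.min(d)
}

# exercise the real command-line entry point in a separate R process
run_cli <- function(args, stdout = TRUE, stdin = "") {
  rscript <- file.path(R.home("bin"), "Rscript")
  code <- sprintf(
    "q(status = bioshade::bioshade_main(c(%s)))",
    paste(sprintf('"%s"', args), collapse = ", ")
  )
  system2(rscript, c("--vanilla", "--default-packages=NULL", "-e",
                     shQuote(code)),
          stdout = stdout, stderr = FALSE, stdin = stdin)
}
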