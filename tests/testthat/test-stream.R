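test_that("highlight_lines strips back to its input for every format", {
  th <- shade_theme("default")
  for (fmt in setdiff(format_ids(), "PLAIN")) {
    fx <- generate_fixture(fmt, seed = 5)
    out <- highlight_lines(fx, fmt, th)
    expect_identical(strip_ansi(out), fx, label = fmt)
    expect_identical(strip_html(highlight_lines(fx, fmt, th, html = TRUE)),
                     fx, label = paste(fmt, "html"))
  }
  # PLAIN passes through untouched
  expect_identical(highlight_lines(c("a", "b"), "PLAIN"), c("a", "b"))
})

test_that("the vectorized SAM body path matches the per-line path byte for byte", {
  th <- shade_theme("default")
  fx <- generate_fixture("SAM", list(n_records = 250, dup_fraction = 0.15),
                         seed = 13)
  slow <- highlight_lines(fx, "SAM", th)
  body <- fx[-(1:5)]
  fast <- bioshade:::render_sam_chunk(body, th)
  expect_identical(fast, slow[-(1:5)])
  # and for the high-contrast theme
  th2 <- shade_theme("high-contrast")
  expect_identical(bioshade:::render_sam_chunk(body, th2),
                   highlight_lines(fx, "SAM", th2)[-(1:5)])
  # short/dirty lines fall back without diverging
  dirty <- c(body[1], "not\ta\tsam\tline", body[2], "x")
  expect_identical(strip_ansi(bioshade:::render_sam_chunk(dirty, th)), dirty)
})

test_that("shade_stream detects formats and reads gzip transparently", {
  fx <- generate_fixture("VCF", seed = 9)
  f <- withr::local_tempfile(fileext = ".vcf.gz")
  con <- gzfile(f, "w")
  writeLines(fx, con)
  close(con)
  sink_file <- withr::local_tempfile()
  out_con <- file(sink_file, "w")
  n <- shade_stream(f, output = out_con)
  close(out_con)
  expect_identical(n, length(fx))
  expect_identical(strip_ansi(readLines(sink_file)), fx)
})

test_that("streaming output equals whole-vector highlighting", {
  fx <- generate_fixture("FASTQ", list(n_records = 100), seed = 21)
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(fx, f)
  sink_file <- withr::local_tempfile()
  out_con <- file(sink_file, "w")
  shade_stream(f, output = out_con, chunk_size = 7L)  # force many chunks
  close(out_con)
  expect_identical(readLines(sink_file), highlight_lines(fx, "FASTQ"))
})

test_that("the CLI renders, forces formats, and lists formats", {
  fx <- generate_fixture("BED", seed = 2)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(fx, f)
  out <- run_cli(c("--no-pager", f))
  expect_identical(strip_ansi(out), fx)
  # forced format overrides the extension
  out2 <- run_cli(c("--no-pager", "--format", "sam", f))
  expect_identical(strip_ansi(out2), fx)
  expect_false(identical(out, out2))
  lst <- run_cli("--list-formats")
  expect_setequal(lst, setdiff(format_ids(), "PLAIN"))
})

test_that("--no-color reproduces the input byte for byte, including gzip", {
  fx <- generate_fixture("SAM", list(n_records = 40), seed = 31)
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(fx, f)
  sink_file <- withr::local_tempfile()
  status <- run_cli(c("--no-color", f), stdout = sink_file)
  expect_identical(status, 0L)
  expect_identical(readBin(sink_file, "raw", file.size(sink_file)),
                   readBin(f, "raw", file.size(f)))
  gz <- withr::local_tempfile(fileext = ".sam.gz")
  con <- gzfile(gz, "w"); writeLines(fx, con); close(con)
  sink2 <- withr::local_tempfile()
  run_cli(c("--no-color", gz), stdout = sink2)
  expect_identical(readLines(sink2), fx)
})

test_that("CLI errors exit 2 with a message, stdin dash reads a pipe", {
  status <- run_cli("nosuchfile.vcf", stdout = FALSE)
  expect_identical(status, 2L)
  expect_identical(run_cli(c("--format", "nope", "-"), stdout = FALSE), 2L)
  fx <- generate_fixture("FASTA", seed = 3)
  f <- withr::local_tempfile()
  writeLines(fx, f)
  out <- run_cli(c("--no-pager", "--format", "fasta", "-"), stdin = f)
  expect_identical(strip_ansi(out), fx)
})

test_that("the fixtures subcommand writes a valid seeded file", {
  f <- withr::local_tempfile(fileext = ".sam")
  status <- run_cli(c("fixtures", "SAM", "--seed", "4", "-o", f,
                      "--n-records", "7"), stdout = FALSE)
  expect_identical(status, 0L)
  expect_identical(readLines(f), generate_fixture("SAM",
                                                  list(n_records = 7),
                                                  seed = 4))
})

test_that("in-package CLI argument handling matches the documented surface", {
  expect_identical(bioshade_main("--list-formats"), 0L)
  expect_identical(bioshade_main(c("--format", "nope")), 2L)
  expect_identical(bioshade_main("nosuchfile.vcf"), 2L)
  # aliases preset the format
  fx <- generate_fixture("GTF", seed = 6)
  f <- withr::local_tempfile()
  writeLines(fx, f)
  sink_file <- withr::local_tempfile()
  out_con <- file(sink_file, "w")
  sink(out_con)
  status <- bioshade_main(c("--no-pager", f), alias = "gtf-less")
  sink()
  close(out_con)
  expect_identical(status, 0L)
  expect_identical(strip_ansi(readLines(sink_file)), fx)
})
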