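prim_test <- list(A = color_spec(0, 255, 0), C = color_spec(255, 0, 0),
                  G = color_spec(255, 160, 0), T = color_spec(0, 0, 255))

test_that("IUPAC codes denote the standard base sets", {
  expect_setequal(iupac_bases("R"), c("A", "G"))
  expect_setequal(iupac_bases("Y"), c("C", "T"))
  expect_setequal(iupac_bases("S"), c("G", "C"))
  expect_setequal(iupac_bases("W"), c("A", "T"))
  expect_setequal(iupac_bases("K"), c("G", "T"))
  expect_setequal(iupac_bases("M"), c("A", "C"))
  expect_setequal(iupac_bases("B"), c("C", "G", "T"))
  expect_setequal(iupac_bases("N"), c("A", "C", "G", "T"))
  expect_identical(iupac_bases("U"), "T")
  expect_identical(iupac_bases("r"), iupac_bases("R"))
  expect_error(iupac_bases("Q"), "IUPAC")
})

test_that("additive mixing follows the ambiguity rules", {
  n <- mix_iupac_color("N", prim_test)
  expect_identical(c(n$r, n$g, n$b), c(255L, 255L, 255L))
  # single bases pass through
  a <- mix_iupac_color("A", prim_test)
  expect_identical(c(a$r, a$g, a$b), c(0L, 255L, 0L))
  # pyrimidine Y mixes red C and blue T into the magenta family
  y <- mix_iupac_color("Y", prim_test)
  expect_identical(y$r, y$b)
  expect_lt(y$g, y$r)
  # M and K are darkened below the mean of their parents
  m <- mix_iupac_color("M", prim_test)
  mean_lum <- (relative_luminance(prim_test$A) +
               relative_luminance(prim_test$C)) / 2
  expect_lt(relative_luminance(m), mean_lum)
  # three-base codes are lightened toward white relative to the raw mean
  b3 <- mix_iupac_color("B", prim_test)
  raw <- round(rowMeans(vapply(prim_test[c("C", "G", "T")],
                               function(p) c(p$r, p$g, p$b), numeric(3))))
  expect_true(all(c(b3$r, b3$g, b3$b) >= raw))
  expect_error(mix_iupac_color("A", prim_test[c("A", "C")]), "primaries")
})

test_that("mixing is invariant under swapping equivalent primaries", {
  swapped <- prim_test[c("A", "C", "G", "T")]
  swapped$A <- prim_test$T
  swapped$T <- prim_test$A
  w1 <- mix_iupac_color("W", prim_test)   # W = {A, T}: mean is symmetric
  w2 <- mix_iupac_color("W", swapped)
  expect_identical(c(w1$r, w1$g, w1$b), c(w2$r, w2$g, w2$b))
})

test_that("PHRED characters decode by offset", {
  expect_identical(phred_score("!"), 0L)
  expect_identical(phred_score("I"), 40L)
  expect_identical(phred_score("~"), 93L)
  expect_identical(phred_score("I", offset = 64), 9L)
  expect_error(phred_score("!", offset = 64), "below")
  expect_error(phred_score("!", offset = 50), "33 or 64")
  expect_error(phred_score("\n"), "printable")
})

test_that("quality binning covers [0,1] with a clamped top bin", {
  expect_identical(quality_bin(0), 0L)
  expect_identical(quality_bin(1), 5L)
  expect_identical(quality_bin(0.5), 3L)
  # boundary enumeration with exactly representable bin edges (k = 4)
  for (i in 0:3) {
    expect_identical(quality_bin(i / 4, k_bins = 4), i)
    if (i > 0) expect_identical(quality_bin(i / 4 - 1e-9, k_bins = 4), i - 1L)
  }
  expect_identical(quality_bin(0.999, k_bins = 2), 1L)
  expect_error(quality_bin(1.2), "\\[0, 1\\]")
  expect_error(quality_bin(0.5, k_bins = 1), "k_bins")
})

test_that("relative luminance uses the sRGB weights", {
  expect_equal(relative_luminance(color_spec(0, 0, 0)), 0)
  expect_equal(relative_luminance(color_spec(255, 255, 255)), 1)
  expect_equal(relative_luminance(color_spec(0, 255, 0)), 0.7152)
  expect_equal(relative_luminance(color_spec(255, 0, 0)), 0.2126)
})

test_that("dichromacy simulation is the configured linear transform", {
  # grays and white lie on the fixed achromatic axis
  for (kind in c("protanopia", "deuteranopia", "tritanopia")) {
    g <- simulate_dichromacy(color_spec(128, 128, 128), kind)
    expect_true(all(abs(c(g$r, g$g, g$b) - 128) <= 1), label = kind)
    w <- simulate_dichromacy(color_spec(255, 255, 255), kind)
    expect_true(all(abs(c(w$r, w$g, w$b) - 255) <= 1), label = kind)
  }
  # direct matrix-vector oracle for pure red under protanopia
  m <- bioshade:::dichromacy_matrices()$protanopia
  expect_equal(rowSums(m), rep(1, 3), tolerance = 0.01)
  v <- pmin(255, pmax(0, round(m %*% c(255, 0, 0))))
  s <- simulate_dichromacy(color_spec(255, 0, 0), "protanopia")
  expect_identical(c(s$r, s$g, s$b), as.integer(v))
  expect_error(simulate_dichromacy(color_spec(1, 2, 3), "monochromacy"))
})

test_that("sequence warmth tracks GC content and ignores order", {
  th <- shade_theme("default")
  expect_gt(sequence_warmth("GGCC", th), sequence_warmth("AATT", th))
  expect_equal(sequence_warmth("NNNN", th), 0)
  expect_equal(sequence_warmth("ACGT", th), sequence_warmth("TGCA", th))
  expect_error(sequence_warmth("", th), "non-empty")
  expect_error(sequence_warmth("ACGZ", th), "non-IUPAC")
})

test_that("amino-acid schemes reproduce their defining groupings", {
  k <- amino_acid_color("K", "clustal")
  r <- amino_acid_color("R", "clustal")
  expect_identical(format(k), format(r))  # basic residues share a colour
  expect_null(amino_acid_color("-", "zappo"))
  expect_null(amino_acid_color("X", "taylor"))
  expect_false(identical(format(amino_acid_color("A", "zappo")),
                         format(amino_acid_color("A", "taylor"))))
  # hydrophobicity endpoints: I hydrophobic red, R hydrophilic blue
  i_col <- amino_acid_color("I", "hydrophobicity")
  r_col <- amino_acid_color("R", "hydrophobicity")
  expect_gt(i_col$r, i_col$b)
  expect_gt(r_col$b, r_col$r)
  expect_error(amino_acid_color("A", "rainbow"))
  expect_error(amino_acid_color("J", "clustal"), "amino-acid")
})

test_that("palette validation reports violations as data", {
  th <- shade_theme("default")
  expect_identical(nrow(validate_nucleotide_theme(th)), 0L)
  bad <- th
  bad$classes[["nucleotide.N"]] <- color_spec(0, 0, 0)
  v <- validate_nucleotide_theme(bad)
  expect_true("N-white" %in% v$constraint)
  bad2 <- th
  bad2$classes[["nucleotide.A"]] <- bad2$classes[["nucleotide.T"]]
  v2 <- validate_nucleotide_theme(bad2)
  expect_true("distinct" %in% v2$constraint)
  bad3 <- th
  bad3$classes[["nucleotide.G"]] <- color_spec(0, 0, 255)  # cool strong base
  expect_true("warmth" %in% validate_nucleotide_theme(bad3)$constraint)
})
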