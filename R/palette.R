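#' IUPAC ambiguity codes and their base sets
#'
#' The 16-letter IUPAC nucleotide alphabet, where each letter denotes a set
#' of the four bases (U is the RNA equivalent of T and denotes \{T\}).
#'
#' @param code A single IUPAC character (case-insensitive).
#' @return A character vector: the subset of `c("A","C","G","T")` denoted.
#' @examples
#' iupac_bases("R")  # purine: A or G
#' iupac_bases("N")  # any base
#' @export
iupac_bases <- function(code) {
  if (!is.character(code) || length(code) != 1 || nchar(code) != 1) {
    stop("expected a single IUPAC character", call. = FALSE)
  }
  key <- toupper(code)
  sets <- iupac_base_sets()
  if (is.null(sets[[key]])) {
    stop("not an IUPAC nucleotide code: ", code, call. = FALSE)
  }
  sets[[key]]
}

iupac_base_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

#' Additive colour for an IUPAC ambiguity code
#'
#' Implements the additive nucleotide colour scheme: the four primary bases
#' are assigned two pairs of contrasting colours, and each ambiguity code is
#' coloured by approximately mixing (channel-wise averaging) the colours of
#' the bases it denotes. Increasing ambiguity gives increasingly lighter
#' tones: three-base codes are lightened towards white by factor `l`, and
#' the fully ambiguous N is pure white. Because four base dimensions have to
#' fit into three colour dimensions, the aMino (M = A/C) and Keto (K = G/T)
#' codes are instead darkened by factor `d` to stay distinct from the other
#' two-base mixes.
#'
#' @param code A single IUPAC character (case-insensitive).
#' @param primaries A named list mapping `"A","C","G","T"` to [color_spec()]s.
#' @param d Darkening multiplier applied to the M and K mixes (0 < d <= 1).
#' @param l Lightening fraction towards white for three-base codes
#'   (0 <= l < 1).
#' @return A [color_spec()].
#' @examples
#' prim <- list(A = color_spec(0, 255, 0), C = color_spec(255, 0, 0),
#'              G = color_spec(255, 160, 0), T = color_spec(0, 0, 255))
#' mix_iupac_color("Y", prim)  # pyrimidine: magenta-family mix of C and T
#' mix_iupac_color("N", prim)  # white
#' @export
mix_iupac_color <- function(code, primaries, d = 0.75, l = 0.35) {
  bases <- iupac_bases(code)  # validates the code
  for (b in c("A", "C", "G", "T")) {
    if (is.null(primaries[[b]])) {
      stop("primaries must map each of A, C, G, T to a colour", call. = FALSE)
    }
  }
  if (length(bases) == 4) {
    return(color_spec(255, 255, 255))
  }
  m <- vapply(primaries[bases],
              function(p) c(p$r, p$g, p$b), numeric(3))
  mix <- rowMeans(m)
  if (length(bases) == 1) {
    p <- primaries[[bases]]
    return(color_spec(p$r, p$g, p$b))
  }
  key <- toupper(code)
  if (key %in% c("M", "K")) {
    mix <- mix * d
  } else if (length(bases) == 3) {
    mix <- mix + (255 - mix) * l
  }
  mix <- pmin(255, pmax(0, round(mix)))
  color_spec(mix[1], mix[2], mix[3])
}

#' PHRED score of a quality character
#'
#' Decodes one ASCII-encoded base or mapping quality character:
#' the score is the code point minus the encoding offset (33 for the
#' standard Sanger/Illumina-1.8+ encoding, 64 for legacy Illumina).
#'
#' @param q A single printable ASCII character.
#' @param offset 33 or 64.
#' @return An integer PHRED score (>= 0).
#' @examples
#' phred_score("!")  # 0
#' phred_score("I")  # 40
#' @export
phred_score <- function(q, offset = 33) {
  if (!is.character(q) || length(q) != 1 || nchar(q) != 1) {
    stop("expected a single character", call. = FALSE)
  }
  if (!offset %in% c(33, 64)) {
    stop("offset must be 33 or 64", call. = FALSE)
  }
  cp <- utf8ToInt(q)
  if (is.na(cp) || cp < 32 || cp > 126) {
    stop("not a printable ASCII character", call. = FALSE)
  }
  s <- cp - as.integer(offset)
  if (s < 0) stop("character below the encoding offset", call. = FALSE)
  s
}

#' Gradient bin for a normalised score
#'
#' Scores (PHRED base quality, mapping quality, BED/GTF scores, VCF QUAL,
#' PDB B-factors) are gradient-coloured: each format normalises its score
#' into \[0, 1\], and this function buckets the normalised value into one of
#' `k_bins` gradient bins selecting the style class `quality.<bin>`.
#'
#' @param score_norm A number in \[0, 1\].
#' @param k_bins Number of gradient bins (>= 2).
#' @return An integer bin index in `0:(k_bins - 1)`.
#' @examples
#' quality_bin(0)    # 0
#' quality_bin(1)    # top bin (clamped)
#' quality_bin(0.5)  # 3 of 6
#' @export
quality_bin <- function(score_norm, k_bins = 6L) {
  if (!is.numeric(score_norm) || length(score_norm) != 1 || is.na(score_norm) ||
      score_norm < 0 || score_norm > 1) {
    stop("score_norm must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(k_bins) || length(k_bins) != 1 || k_bins < 2) {
    stop("k_bins must be >= 2", call. = FALSE)
  }
  min(as.integer(floor(score_norm * k_bins)), as.integer(k_bins) - 1L)
}

#' Relative luminance of a colour
#'
#' The sRGB-weighted luminance `0.2126 R + 0.7152 G + 0.0722 B` on channels
#' scaled to \[0, 1\]. Channel linearisation is deliberately omitted: the
#' package only uses luminance for ordering (gradient monotonicity) and
#' separation (accessibility margins), for which the weighted sum suffices.
#'
#' @param c A [color_spec()].
#' @return A number in \[0, 1\].
#' @examples
#' relative_luminance(color_spec(0, 255, 0))  # 0.7152
#' @export
relative_luminance <- function(c) {
  stopifnot(inherits(c, "shade_color"))
  0.2126 * (c$r / 255) + 0.7152 * (c$g / 255) + 0.0722 * (c$b / 255)
}

#' Simulate dichromatic colour vision
#'
#' Applies a published 3x3 linear RGB transform approximating how a colour
#' appears under protanopia, deuteranopia or tritanopia. The matrices ship
#' as configuration (`inst/palettes/dichromacy.yaml`) with provenance noted
#' there; their rows sum to ~1, so achromatic colours are (approximately)
#' fixed points. Channels are clamped to \[0, 255\] after the transform.
#'
#' @param c A [color_spec()].
#' @param kind One of `"protanopia"`, `"deuteranopia"`, `"tritanopia"`.
#' @return A [color_spec()] for the simulated appearance.
#' @examples
#' simulate_dichromacy(color_spec(255, 0, 0), "protanopia")
#' @export
simulate_dichromacy <- function(c, kind) {
  stopifnot(inherits(c, "shade_color"))
  m <- dichromacy_matrices()[[match.arg(kind, names(dichromacy_matrices()))]]
  v <- m %*% c(c$r, c$g, c$b)
  v <- pmin(255, pmax(0, round(v)))
  color_spec(v[1], v[2], v[3], bold = c$bold, bg = c$bg)
}

dichromacy_cache <- new.env(parent = emptyenv())

dichromacy_matrices <- function() {
  if (is.null(dichromacy_cache$m)) {
    path <- system.file("palettes", "dichromacy.yaml", package = "bioshade",
                        mustWork = TRUE)
    raw <- yaml::read_yaml(path)
    dichromacy_cache$m <- lapply(raw$matrices, function(rows) {
      do.call(rbind, rows)
    })
  }
  dichromacy_cache$m
}

#' Warm-vs-cool score of a colour or sequence
#'
#' The nucleotide palette is built so that the strong bases G and C are warm
#' and the weak bases A and T are cool; a sequence's average warmth then
#' approximates its GC content at a glance. Warmth of one colour is
#' `(r - b) / 255` in \[-1, 1\]; sequence warmth is the mean warmth of the
#' theme colours of its IUPAC codes.
#'
#' @param seq A non-empty string of IUPAC nucleotide codes.
#' @param theme A [shade_theme()].
#' @return A number in \[-1, 1\].
#' @examples
#' th <- shade_theme("default")
#' sequence_warmth("GGCC", th) > sequence_warmth("AATT", th)
#' @export
sequence_warmth <- function(seq, theme) {
  stopifnot(inherits(theme, "shade_theme"))
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop("seq must be a non-empty string", call. = FALSE)
  }
  chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
  if (!all(chars %in% iupac_codes)) {
    stop("seq contains non-IUPAC characters: ",
         paste(unique(chars[!chars %in% iupac_codes]), collapse = ""),
         call. = FALSE)
  }
  w <- vapply(chars, function(ch) {
    col <- theme$classes[[paste0("nucleotide.", ch)]]
    color_warmth(col)
  }, numeric(1))
  mean(w)
}

color_warmth <- function(c) (c$r - c$b) / 255

#' Check a theme's nucleotide palette constraints
#'
#' Validates the constraints that make the additive IUPAC palette readable:
#' (i) N is pure white; (ii) the strong bases G and C are warm
#' (`warmth > 0`) and the weak bases A and T are cool (`warmth < 0`);
#' (iii) the aMino (M) and Keto (K) colours are darker than the mean of
#' their parent primaries; (iv) all 16 IUPAC colours are pairwise distinct.
#' Violations are returned as data, not raised: palette checking is a
#' linting step.
#'
#' @param theme A [shade_theme()] with entries for all `nucleotide.*` classes.
#' @return A tibble with columns `constraint` and `detail`; zero rows when
#'   the theme satisfies every constraint.
#' @examples
#' validate_nucleotide_theme(shade_theme("default"))  # 0 rows
#' @export
validate_nucleotide_theme <- function(theme) {
  stopifnot(inherits(theme, "shade_theme"))
  nt <- function(ch) theme$classes[[paste0("nucleotide.", ch)]]
  bad <- list()
  note <- function(constraint, detail) {
    bad[[length(bad) + 1]] <<- tibble::tibble(constraint = constraint,
                                              detail = detail)
  }
  n_col <- nt("N")
  if (is.null(n_col) || n_col$r != 255 || n_col$g != 255 || n_col$b != 255) {
    note("N-white", "the fully ambiguous base N must be pure white")
  }
  for (warm in c("G", "C")) {
    if (color_warmth(nt(warm)) <= 0) {
      note("warmth", paste0("strong base ", warm, " must be warm (r > b)"))
    }
  }
  for (cool in c("A", "T")) {
    if (color_warmth(nt(cool)) >= 0) {
      note("warmth", paste0("weak base ", cool, " must be cool (r < b)"))
    }
  }
  parent_mean_lum <- function(b1, b2) {
    (relative_luminance(nt(b1)) + relative_luminance(nt(b2))) / 2
  }
  if (relative_luminance(nt("M")) >= parent_mean_lum("A", "C")) {
    note("amino-keto-dark", "M must be darker than the mean of A and C")
  }
  if (relative_luminance(nt("K")) >= parent_mean_lum("G", "T")) {
    note("amino-keto-dark", "K must be darker than the mean of G and T")
  }
  hexes <- vapply(iupac_codes, function(ch) {
    col <- nt(ch)
    if (is.null(col)) NA_character_ else rgb_to_hex(col$r, col$g, col$b)
  }, character(1))
  if (anyNA(hexes)) {
    note("totality", paste0("missing nucleotide entries: ",
                            paste(iupac_codes[is.na(hexes)], collapse = ", ")))
  } else if (anyDuplicated(hexes)) {
    dup <- hexes[duplicated(hexes)]
    note("distinct", paste0("duplicated RGB among IUPAC codes: ",
                            paste(names(hexes)[hexes %in% dup], collapse = ", ")))
  }
  if (length(bad) == 0) {
    tibble::tibble(constraint = character(), detail = character())
  } else {
    do.call(rbind, bad)
  }
}

#' Colour of an amino-acid residue under a published scheme
#'
#' Looks up a residue in one of four published amino-acid colour schemes:
#' CLUSTAL (ClustalX groups: basic, acidic, polar, hydrophobic...), Taylor,
#' Zappo, or hydrophobicity. The tables ship as configuration
#' (`inst/palettes/aa-schemes.yaml`). Gaps and unknown residues (X) render
#' unstyled.
#'
#' @param residue A one-letter residue code (20 standard plus B, Z, X) or a
#'   gap character (`-`, `.`, `*`).
#' @param scheme One of `"clustal"`, `"taylor"`, `"zappo"`,
#'   `"hydrophobicity"`.
#' @return A [color_spec()], or `NULL` for an unstyled residue/gap.
#' @examples
#' amino_acid_color("K", "clustal")
#' identical(format(amino_acid_color("K", "clustal")),
#'           format(amino_acid_color("R", "clustal")))  # basic group shares
#' @export
amino_acid_color <- function(residue, scheme = c("clustal", "taylor", "zappo",
                                                 "hydrophobicity")) {
  scheme <- match.arg(scheme)
  if (!is.character(residue) || length(residue) != 1 || nchar(residue) != 1) {
    stop("expected a single residue character", call. = FALSE)
  }
  key <- toupper(residue)
  if (key %in% c("-", ".", "*", "X")) return(NULL)
  if (!key %in% aa_codes) {
    stop("not an amino-acid code: ", residue, call. = FALSE)
  }
  tab <- aa_scheme_tables()[[scheme]]
  hex <- tab[[key]]
  if (is.null(hex)) return(NULL)
  v <- hex_to_rgb(hex)
  color_spec(v[1], v[2], v[3])
}

aa_scheme_cache <- new.env(parent = emptyenv())

aa_scheme_tables <- function() {
  if (is.null(aa_scheme_cache$t)) {
    path <- system.file("palettes", "aa-schemes.yaml", package = "bioshade",
                        mustWork = TRUE)
    aa_scheme_cache$t <- yaml::read_yaml(path)$schemes
  }
  aa_scheme_cache$t
}
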