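---
title: "How bioshade colours biological text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How bioshade colours biological text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioshade)
```

## The model: lines, tokens, classes, themes

bioshade treats a biological text file as a stream of independent lines.
For each line, a format-specific lexer emits *tokens*: sorted,
non-overlapping `[start, end)` byte spans, each carrying one member of a
closed set of *biological style classes* (`style_classes()`). The class
set is deliberately cross-format: a chromosome name or position is the
`coordinate` class whether it appears in a BED interval, a GTF feature, a
SAM alignment or a VCF record, so a single reserved colour identifies
genomic coordinates everywhere. Sample identifiers share `sample-info`,
CIGAR operations map to `cigar.*` classes, every IUPAC nucleotide code has
its own `nucleotide.*` class, and scores of any origin share the
`quality.*` gradient bins.

A *theme* is a total mapping from style classes to colours; rendering is
then a mechanical insertion of ANSI SGR escapes (or HTML spans) at token
boundaries. Three invariants shape the whole design:

* **Losslessness.** Content bytes are emitted unchanged and in order;
  stripping escapes recovers the input exactly. The highlighter is a
  viewer, never a rewriter — coordinates are not reinterpreted, bytes are
  classified in place.
* **Totality.** No input can crash the lexer. Malformed spans get the
  `unknown` class, which every theme maps to "no styling". A pager
  wrapper that dies on dirty data is useless.
* **Statelessness per line.** Only a tiny `lex_state` (header flag,
  FASTQ phase, sniffed FASTA alphabet) crosses line boundaries, so memory
  is O(chunk), independent of stream length, and files of any size can be
  piped through.

## The additive IUPAC nucleotide palette

The four primary bases are coloured as two contrasting pairs chosen so
that additive mixing encodes ambiguity: an ambiguity code's colour is the
channel-wise mean of the primaries of the bases it denotes
(`mix_iupac_color()`). The fully ambiguous N is pure white. Because four
base dimensions cannot embed in three colour dimensions, the aMino
(M = A/C) and Keto (K = G/T) mixes are darkened by a factor `d`
(default 0.75), while three-base codes are lightened towards white by a
fraction `l` (default 0.35) — one consistent reading of "increasingly
lighter tones with increasing ambiguity". Both factors are free
parameters of the mixer; the shipped theme files freeze the resulting 16
colours as data. U denotes the same base as T and is nudged slightly
lighter in the shipped themes so all 16 entries stay pairwise distinct.

Two perceptual conventions are enforced rather than assumed, by
`validate_nucleotide_theme()`:

* the strong bases G and C are *warm* (red channel above blue) and the
  weak bases A and T are *cool*, so a sequence's average warmth
  (`sequence_warmth()`, defined as mean `(r - b)/255`) approximates its
  GC content at a glance;
* N is white, M/K are darker than the mean of their parents, and all 16
  codes are distinct.

Warmth is a deliberately minimal operationalisation of "warm vs cool" —
a single signed channel difference — sufficient to make the GC-content
claim testable without a perceptual colour-appearance model.

```{r}
validate_nucleotide_theme(shade_theme("default"))
sequence_warmth("GGCCGGCC", shade_theme("default"))
sequence_warmth("AATTAATT", shade_theme("default"))
```

## Quality gradients

Scores are gradient-coloured in six luminance-monotone bins
(`quality_bin()`). Each producer normalises to [0, 1] before binning;
the divisors are this package's choices, as no convention exists:
PHRED base qualities /40 (the usual Illumina ceiling), SAM MAPQ /60
(the common aligner maximum), BED and GTF scores /1000 (the UCSC range),
VCF QUAL /100, PDB B-factors /100, all capped at 1. The gradient bins are
shared classes, so "low quality" looks the same in a FASTQ quality
string, a mapping quality column and a B-factor field.

## Colour-blind accessibility

The high-contrast theme separates A, C, G, T and N primarily by
lightness: any two of them differ in relative luminance by at least 0.15,
and this margin survives simulated protanopia, deuteranopia and
tritanopia (`simulate_dichromacy()`, a 3×3 linear RGB transform whose
matrices ship as YAML config with their provenance noted). Luminance here
is the sRGB-weighted sum without channel linearisation — adequate for
ordering and separation margins, which is all the package asserts.

The high-contrast primaries were found by a randomised search over
warmth-constrained colours maximising the worst-case post-simulation
luminance gap; the winning set (margin ≈ 0.18) is frozen in
`inst/themes/high-contrast.yaml`.

## Lexing decisions worth knowing

* Offsets are byte offsets on the raw line. ASCII lines take a fast
  path; valid multi-byte UTF-8 is lexed in character space and remapped
  to byte offsets, so escapes are never inserted inside a character.
  Invalid byte sequences degrade to a single `unknown` token.
* A trailing carriage return is excluded from every token.
* SAM `=` and `.` in SEQ reuse the fully ambiguous nucleotide class
  rather than a bespoke class, keeping the nucleotide class set equal to
  the IUPAC set.
* Fields the format specifications define but that carry no biological
  emphasis here (SAM TLEN, VCF ID and FILTER) are left unstyled.
* GTF lines whose feature is CDS, UTR, start_codon or stop_codon carry a
  line-level background class: the renderer paints the whole line's
  background while field tokens keep their own foregrounds, so
  protein-coding records stand out as blocks.
* Headerless SAM simply starts in body mode at the first non-`@` line;
  once a body line is seen the header state never returns.

## Rendering and throughput

`render_ansi()` emits one SGR sequence per styled region (adjacent
same-class tokens are coalesced), resets before any unstyled span that
follows styling, and always closes a styled line with a reset so pagers
never bleed colour. Only palette indices 16–255 are used — the 16 system
colours depend on the user's terminal theme. `ansi256_of_rgb()` maps RGB
to the 6×6×6 cube plus grayscale ramp by exact nearest-neighbour search
with lowest-index tie-breaking, so the derivation is deterministic and
idempotent.

Streaming (`shade_stream()`, and the `bioshade`/`sam-less` launchers)
reads fixed-size chunks (4000 lines by default). SAM bodies — the
format where whole-genome streams are routinely paged — additionally use
a vectorized chunk renderer that produces byte-identical output to the
per-line path for well-formed records; lines needing byte-level care
fall back individually. On one CPU this sustains roughly 10,000 alignment
lines per second with a memory high-water mark set by the chunk size,
not the stream length.

## What the synthetic fixtures do and do not show

`generate_fixture()` produces seeded, format-valid files: SAM with a
header, consistent SEQ/QUAL lengths, a configurable PCR-duplicate
fraction (identical sequence and position, duplicate FLAG bit) and 2%
IUPAC ambiguity so every nucleotide colour path is exercised; FASTQ with
a linear per-position quality decay (start 38, ~0.25 per cycle, noise
SD 3, clamped to [2, 40]); VCF/BED/GTF with plausible coordinates and
attributes; fixed-column PDB ATOM records; a CLUSTAL block with a
conservation line. They emulate the *shape* of real data, not its
biology: there is no reference genome, no alignment semantics, no linkage
between records. Tests passing on fixtures therefore demonstrate format
handling and rendering invariants — including on fuzzed byte garbage —
but say nothing about biological plausibility, and real-world files can
still present dialect quirks (e.g. exotic header tags) that simply fall
back to `unknown`/unstyled rendering.

Problem sizes used by the test suite and the acceptance script — 1000
fuzzed lines per format for losslessness, 10,000 for lexer totality,
1000 CIGARs each way, 100 twenty-mers per GC level, and one
100,000-line SAM stream — were chosen to exercise each property well
past its small-sample noise while keeping a full run in the order of a
minute on a single CPU.

## Known limitations

* No BAM/BCF decoding (pipe `samtools view -h` output), no GFF3, no
  semantic validation of records.
* True-colour (24-bit) output is not emitted; the ANSI-256 quantisation
  is the terminal contract.
* The editor-integration side of syntax highlighting (vim/gedit/Sublime/
  VSCode definition files) is out of scope; this package is the pager
  and library implementation.
* `-x N` is forwarded to the pager as its tab-stop option; bioshade
  itself never expands tabs.
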