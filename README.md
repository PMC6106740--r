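# bioshade

Syntax highlighting for the plain-text file formats of computational
biology, in R, from the terminal.

Much of day-to-day bioinformatics is *reading* raw data: SAM alignments
piped out of `samtools view -h`, VCF variant records, GTF annotations,
FASTA/FASTQ sequence files, PDB structures, CLUSTAL alignments. These
formats are easy to parse by machine and hard to scan by eye — dense
tab-delimited rows, verbose headers, run-length CIGAR strings, quality
strings in ASCII armour. bioshade is a streaming syntax highlighter for
that reading workload: it lexes each line into byte spans carrying
*biological* style classes and renders them as ANSI-coloured text for a
terminal or pager (`less -R`), or as HTML.

The class system is unified across formats: a genomic coordinate gets the
same reserved colour in BED, GTF, SAM and VCF; sample information, read
names, CIGAR operation types, per-base nucleotide identities and score
gradients are likewise shared classes, so knowing one format's colours
teaches you the next one. For whom: anyone who spends time with `less`,
`grep` and a pipe on genomic text files.

## The colour model in brief

* **Additive IUPAC palette.** The four primary bases are two contrasting
  colour pairs; an ambiguity code's colour is the channel mean of the
  bases it denotes — for code $X$ with base set $B(X) \subseteq
  \{A,C,G,T\}$, $c(X) = \mathrm{mean}_{b \in B(X)}\, c(b)$ — with N white,
  the M/K mixes darkened by $d = 0.75$, and three-base codes lightened
  towards white by $l = 0.35$. Strong bases (G, C) are warm, weak bases
  (A, T) cool, so mean warmth $(r - b)/255$ approximates GC content at a
  glance.
* **Quality gradients.** Any score (PHRED base quality, MAPQ, BED/GTF
  score, VCF QUAL, PDB B-factor) is normalised to $[0,1]$ and binned into
  $k = 6$ luminance-monotone gradient classes:
  $\mathrm{bin}(s) = \min(\lfloor s\,k \rfloor,\, k - 1)$.
* **Accessibility.** A high-contrast theme keeps every pair of
  {A, C, G, T, N} at least 0.15 apart in relative luminance
  ($0.2126R + 0.7152G + 0.0722B$), before *and* after simulated
  protanopia, deuteranopia and tritanopia.
* **Losslessness.** Rendering only inserts SGR escapes; stripping them
  recovers the input byte for byte, and `--no-color` is the identity.

## Worked example

```r
library(bioshade)

# a small seeded alignment file (any supported format can be generated)
sam <- generate_fixture("SAM", list(n_records = 3, read_length = 20), seed = 1)
writeLines(sam[6])
#> read00001  0  chr1  124413  42  6M2I12M  *  0  0  CCTAGATGAGGCTCAACAGA  GFBEGIEFEACCDGFCBED@  NM:i:0  RG:Z:rg1

# lexing: byte spans with cross-format biological classes
lex_line(lex_state("SAM"), "@SQ\tSN:chr1\tLN:248956422")$tokens
#> # A tibble: 5 × 3
#>   start   end class      
#>   <int> <int> <chr>      
#> 1     0     3 record-type
#> 2     4     6 meta-key   
#> 3     7    11 meta-value 
#> 4    12    14 meta-key   
#> 5    15    24 meta-value 

parse_cigar("10M1I5M2S")
#> # A tibble: 4 × 2
#>   length op   
#>    <int> <chr>
#> 1     10 M    
#> 2      1 I    
#> 3      5 M    
#> 4      2 S    

# rendering: ANSI escapes around each classified span
out <- highlight_lines(sam, "SAM")
cat(substr(out[6], 1, 90), "\n")
#> \033[0;38;5;180mread00001\033[0m  \033[0;38;5;173m0\033[0m  \033[0;1;38;5;29mchr1\033[0m  \033[0;1;38;5;29m124413\033[0m ...
identical(strip_ansi(out), sam)
#> [1] TRUE

# warm = GC-rich, cool = AT-rich
th <- shade_theme("default")
sequence_warmth("GGCCGGCC", th)   #>  0.8784314
sequence_warmth("AATTAATT", th)   #> -0.6941176

validate_nucleotide_theme(th)     #> 0 rows: all palette constraints hold
ggplot2::autoplot(th)             # palette tiles + gradient ramp
```

The token values shown are what the code prints: the SAM header line
splits into a record-type tag, `SN`/`LN` keys and their values; body
fields map to read-name, flag, coordinate, gradient-binned MAPQ, per-op
CIGAR spans, per-base sequence and per-character quality tokens.

## Command line

Thin launchers ship in `inst/exec` (`bioshade` plus the aliases
`sam-less`, `vcf-less`, `gtf-less`, `bed-less`, `fa-less`, `fq-less`,
`pdb-less`, `aln-less`):

```sh
samtools view -h NA12878.bam | sam-less -
gzip -dc gencode.v26.gtf.gz | grep 'MYC' - | gtf-less -x 10
bioshade --theme high-contrast --format vcf calls.vcf.gz
bioshade fixtures fastq --seed 7 -o example.fastq
```

Format comes from the file extension (a trailing `.gz` is stripped),
content sniffing, a forced `--format`, or the alias name; gzip input is
decompressed transparently; a pager is spawned only when stdout is a
terminal; `--no-color` copies input through byte-identically; unreadable
files exit 2 with a message on stderr.

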