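---
title: "Methods: start-codon context analysis with bacscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: start-codon context analysis with bacscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacscan)
```

## The scientific problem

Ribosomes do not use every AUG equally well. The nucleotides flanking a
translation initiation site (TIS) — by convention the A of the AUG is +1,
upstream positions are negative and there is no position 0 — modulate how
reliably the scanning 43S preinitiation complex commits to a start codon.
The classical vertebrate result is that a purine at −3 and a G at +4 mark
*strong* contexts, and `bacscan` encodes the standard four-way rule:

* **optimal**: the full `GCCRCCAUGG` context (requires six upstream bases);
* **strong**: −3 ∈ {A, G} and +4 = G;
* **moderate**: exactly one of the two key positions holds;
* **weak**: −3 ∈ {C, U} and +4 ≠ G.

Beyond the classes, a small set of specific *weak* 7-mers — the eight
**barren AUG context sequences** (BACS:
`r paste(bacsSequences(), collapse = ", ")`) — disfavour translation far
more strongly than weakness alone predicts, consistently across rabbit,
fruit fly and wheat reporter assays. The package's purpose is to make
every computational step of that discovery reproducible: reporter
normalisation, percentile splits, enrichment logos, degenerate-motif
statistics, and the genome-wide scan for BACS-containing genes.

## Reporter normalisation and ranking

Dual-luciferase measurements arrive as per-well firefly (FLuc) relative
light units, with each 96-well plate carrying control wells expressing
Renilla luciferase (RLuc) from an IRES-driven control mRNA.
`normalizePlates()` divides each well by the *mean* RLuc reading of its
plate; this is the only batch correction applied, and it makes the
normalised values invariant to any common rescaling of a plate (a
property the tests assert). `summarizeContexts()` averages the
(typically three) replicate wells per context.

`rankAndSplit()` orders contexts by mean activity and takes the extreme
`round(fraction * n)` of them. Two numerical choices matter and are
deliberate:

* the count is rounded **half-up** (`floor(k + 0.5)`), because base R's
  `round()` rounds halves to even, which would make a 0.5 boundary
  contexts-count depend on parity;
* ties at the cut are broken by **ascending context id**, so splits are
  deterministic and reruns are byte-identical.

Group comparisons (`motifFoldChange()`) report the ratio of group
**means** of per-context mean activities by default; the source data do
not pin down mean versus median aggregation, so a `median` option is
exposed rather than hidden. The accompanying test is a Wilcoxon rank-sum
(Mann–Whitney) test: exact when the pooled size is at most 12 with no
ties, otherwise the normal approximation with tie and continuity
correction (delegated to `stats::wilcox.test`; the test suite checks it
against an independent full-enumeration oracle). Two-sidedness is used
throughout since the source reports only `P <` bounds.

## The enrichment-logo statistic

For a selected subset of contexts against a background set, the logo
statistic per nucleotide $i$ and position $k$ is

$$E_{set}[i,k] = P_{set}[i,k] \cdot \log_2\!\frac{P_{set}[i,k]}{P_{back}[i,k]}$$

with probabilities computed from counts after adding a pseudocount of
0.01 *per nucleotide per position* (the alignment-to-matrix convention;
applied to counts, not probabilities, so ports match at double
precision). $E$ is defined as 0 where $P_{set} = 0$ — the limit of
$x \log x$ — which keeps degenerate subsets finite. Positive values mark
enrichment in the subset, negative values depletion. The default
positions are −3, −2, −1 and +4, the experimentally varied window; any
anchored position set is accepted.

Reading a consensus off a logo by eye is not reproducible, so
`callConsensus()` formalises it: per position, nucleotides are sorted by
probability and the smallest prefix whose cumulative probability reaches
a threshold (default 0.75) becomes the IUPAC code, with probability ties
included together. The call is monotone in the threshold (raising it
never drops a nucleotide), and 0.75 recovers two-letter codes such as Y
and M on pyrimidine-dominated bottom fractions.

## The anchored motif engine

All motifs here are anchored to the start codon (`YCMAUGY`, `YNNAUGY`,
`GCCRCCAUGG`, …); free-floating scanning is deliberately unsupported
because it would invite off-target matches. Patterns parse from text
with exactly one `AUG`/`ATG` anchor, expand to their concrete-sequence
sets, match contexts position-by-position, and emit plain bracket-class
regexes (`[CT]C[AC]ATG[CT]` for YCMAUGY on DNA) that round-trip through
the parser. BACS membership itself is an **exact 7-mer lookup**, not a
degenerate pattern: the eight sequences are not expressible as one IUPAC
word, and treating them as `YCMAUGY` would both over- and under-count.

## Genome scanning

`extractTisContexts()` reads FASTA + GFF3 (via Biostrings and
rtracklayer; GFF3 coordinates are 1-based inclusive) and emits one
context per gene: three bases upstream, the codon, and the first coding
base after it, in transcript orientation (minus-strand genes are
reverse-complemented). Decisions the annotation format forces:

* **representative transcript**: the mRNA with the longest total CDS
  (ties by transcript id); `per_transcript` and `per_unique_context`
  policies are available;
* **upstream flank**: genomic bases immediately 5′ of the codon by
  default — a deliberate mirror of naive start-codon extraction — with a
  `spliced = TRUE` option that walks annotated 5′UTR exons instead;
* **+4 across introns**: when the codon ends a CDS segment, the +4 base
  comes from the next segment and the record is flagged
  `joined_over_intron`;
* **edge and non-AUG cases**: contexts running off a contig
  (`truncated_upstream`/`truncated_downstream`) and annotated non-AUG
  starts (`non_aug_start`) are flagged and excluded from pattern counts
  rather than silently dropped.

`summarizeGO()` bins pattern-hit genes by gene-ontology category using
an editable two-column map (GO id → category) whose *file order defines
priority* when a gene carries several GO ids; unmapped genes fall into
`diverse`. The bundled seed map puts GO:0016021 (integral component of
membrane) first, the most represented category among BACS-containing
genes. Annotation arrives as a plain gene → GO TSV; protein-similarity
GO transfer is out of scope.

## The synthetic assay generator

Real measurements cannot ship with the package, so `simulateAssay()`
generates well tables with the statistical structure the analysis
assumes: per-well log10 activity is a species baseline plus additive
per-position nucleotide effects plus a penalty for a designated barren
set, plus Gaussian noise on the log scale — i.e. multiplicative
log-normal noise on raw light units, which is how luminometer readings
actually vary. Raw FLuc is scaled by the plate's realised control level,
so the per-plate normalisation step has real work to do; at zero noise
the whole pipeline returns planted values exactly, which the tests
exploit. Plates hold 30 contexts in triplicate plus control wells, and
everything is determined by one seed.

The `paperlikeParams()` preset (−3 A strongest, +4 G favoured, a
log10(1/25) BACS penalty, noise SD 0.15) produces strong-over-weak
separation with top/bottom-20% ratios on the order of hundreds — the
same regime as real cell-free reporter panels — without claiming to
reproduce any measured number. What the generator does **not** emulate:
position interactions are off by default (real −1/−2 effects depend on
the other positions), there are no plate edge effects, no
heteroscedastic detector floor, and no leaky-scanning mechanics — it is
phenomenological. Passing recovery tests therefore show the *analysis*
is correct and well-calibrated, not that the biological model is.

`simulateToyGenome()` plants genes with known contexts on both strands
of multi-gene contigs and deliberately includes the awkward cases:
the first gene of each contig has a truncated upstream flank, a fraction
of genes (default 10%) have an intron directly after the start codon,
and a small fraction (default 0.5%) carry annotated GUG starts. The
truth table lets tests demand exact agreement for every non-flagged
gene.

## Problem sizes and reproduction

The test suite and the acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
work at sizes chosen to exercise every code path while keeping runs
quick: 120-context panels in triplicate for recovery experiments (100
seeds for fold-change recovery, 20 for consensus calling), and
2000-gene simulated genomes for the scanner. Two comparisons need data
that cannot be bundled — the article's per-well measurement export and
the three pinned RefSeq assemblies (`GCF_000001215.4`,
`GCF_000003625.3`, `GCF_018294505.1`). The corresponding tests document
the expected file locations under `tests/testthat/external/` and fail
until those inputs are supplied; they are not skipped, so their status
is always visible.

## Known limitations

* The Kozak rule set models only −3, −2, −1 and +4; positions −4…−10 and
  +5/+6 (minor or absent effects in vertebrates) are out of scope, as
  are near-cognate (non-AUG) starts.
* `optimal` is only ever returned with six or more upstream bases; a
  7-mer context can at best be called `strong`, since optimality cannot
  be established from three upstream bases.
* The genome scanner assumes the standard genetic code and annotated
  CDS features with gene/mRNA parentage; isoform quantification and
  annotation transfer are out of scope.
* The printed panel contains internal count discrepancies (a stated
  total of 152 primer sequences versus 150 countable tested rows of
  160). The bundled fixture reproduces the table as printed and all
  counts are computed from it, never hard-coded.
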