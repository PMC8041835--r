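---
title: "Methods: G-quadruplex motif discovery and distribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex motif discovery and distribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4tools)
```

## The model

G-quadruplexes (G4s) are four-stranded nucleic-acid structures formed by
stacked planar quartets of guanines. A sequence can fold into a G4 when it
carries at least four runs of guanines (G-stems) separated by short loops.
`g4tools` predicts such motifs from sequence alone, using the pattern
conventions of the quadparser lineage:

* **Perfect motifs**: `(G{3,} L{1-7}){3,} G{3,}` — at least four runs of
  three or more Gs, separated by loops of 1–7 arbitrary bases
  (`scan_perfect()`).
* **Multimeric motifs**: the same pattern with at least eight G-stems,
  candidates for stacked/tandem quadruplexes (`scan_multimeric()`).
* **Imperfect (bulged) motifs**: stems of exactly 3–4 guanines that may be
  interrupted by a single bulge of 1–2 non-G bases, chained by loops of up
  to 7 bp (class `imperfect`) or up to 12 bp (`imperfect_long`)
  (`scan_imperfect()` + `merge_overlapping()`).

Both strands are always screened: the antisense search matches the
complementary C-pattern on the forward sequence, keeps forward coordinates,
reports `strand = "-"`, and gives `motif_seq` 5'→3' on the motif strand.
All public coordinates are 0-based half-open (BED convention); GFF3 input is
converted on read.

## Matching semantics and numerical choices

* **Leftmost, greedy, non-overlapping.** Matches per strand are found
  leftmost-first with maximal extension, and the search resumes at the
  previous match end, so a continuous G4-dense stretch is counted once.
  Forward and reverse motifs may overlap each other; motifs on one strand
  never do. The test suite proves this equal to an exhaustive
  substring-testing enumerator on hundreds of random sequences.
* **Stem counting.** `count_stems()` reports the *maximal* number of repeat
  units over all decompositions of the matched span. This choice (rather
  than the units a backtracking engine happens to commit to) is what makes
  an eight-run multimeric span report eight stems even though greedy loops
  could swallow whole G-runs and yield a five-unit parse of the same span.
* **N handling.** `N` is accepted in loops but terminates G-runs, so
  assembly gaps can never fabricate a stem. Input is uppercased; lowercase
  soft-masking is not treated as masking.
* **Bulge semantics.** The bulge budget is per stem (at most one bulge of
  1–2 non-G bases per stem), not per motif; bulge bases must be non-G since
  a G would simply extend the block. Loops are at least 1 bp: stems never
  touch.
* **Candidate merging.** Imperfect enumeration reports maximal-coverage
  candidate spans per starting stem; only the per-strand union of candidates
  (overlapping or book-ended intervals merged) is contract-stable, and that
  merged set is what the brute-force oracle is compared against. Merging
  never crosses strands.
* **Moving averages.** Profile smoothing uses a centered mean with
  shrinking windows at the array edges (no zero padding, which would
  fabricate dilution at the boundaries). `window = 1` is the identity.
  Local-maximum counting is plateau-aware and quantises values to an 1e-8
  relative tolerance to absorb running-sum floating-point jitter.
* **Density and frequency.** Density is motifs per Mb of *unioned* region
  span. Positional frequency tallies every covered base at its
  gene-oriented offset (a per-motif-start mode exists behind
  `mode = "start"`); dividing by the number of anchored regions gives the
  per-position fraction and `per_Mb` multiplies that fraction by 1e6. Both
  the raw and normalised scales are available because published y-axes of
  this kind are rarely defined formulaically.
* **Genic density denominators.** "Genic" can mean gene bodies only or
  bodies plus 500-bp UTR-proxy flanks; `g4_density()` takes an explicit
  region table so both framings can be computed and labelled side by side.

## Feature assignment and peaks

Gene models come from GFF3 (first transcript per gene, in file order;
models without CDS are kept and flagged). Assignment categories are the 1-kb
windows upstream of the start codon and downstream of the gene, the 500-bp
UTR-proxy flanks, the gene body, and first-vs-rest CDS and intron blocks in
transcription order; any 1-bp overlap qualifies, and `cds_first`/`cds_rest`
(likewise introns) are mutually exclusive per motif-gene pair. The
gene-relative strand (`sense`/`antisense`) is recorded alongside the
absolute strand.

The three peak regions scored by `peak_gene_sets()` are gene-oriented
windows on the antisense strand: `[-250, 0)` before the start codon
(5' UTR side), `[0, +250)` after it (first CDS), and the first 100 bp of
intron 1 (multi-exon genes only). Sets may intersect when a motif spans a
boundary.

## Enrichment and GO statistics

Fold enrichment places each region uniformly at random (chromosome chosen
proportional to length among those it fits, start uniform; intervals may
overlap; no exclusion zones) and divides the observed motif overlap by the
mean shuffled overlap. One replicate reproduces the single-shuffle
procedure; `n_reps` exposes replicate variance for calibration. The iid
background generator builds three independent uniform-composition datasets
and keeps the median density.

GO association uses a per-term 2×2 Pearson chi-square over the gene universe
(no continuity correction by default — a flag enables Yates), with
Benjamini–Hochberg q-values and a flag for tables with any expected cell
below 5. Over-representation uses the hypergeometric upper tail. Terms are
tested as annotated; no propagation up the ontology graph is attempted.

## SNP disruption

A SNP inside a motif is located in the maximal-stem parse: loop and ±10-bp
flank positions are `loop_or_flank`; stem positions are applied to the
local sequence (motif ±10 bp) and the same strand is rescanned — if a
perfect motif still overlaps the original span (alternative stems, or a
4-G run sliding off the variant) the SNP is `stem_tolerated`, otherwise
`stem_disruptive`. A SNP whose alternate allele equals the reference can
never be called disruptive.

## The synthetic genome generator

`generate()` produces the desk-scale substrate every analysis is tested on:

1. **Background**: iid sequence at a target GC (default 0.44, a
   Triticeae-like genome average), then *scrubbed* of spurious perfect
   motifs on both strands by mutating the middle base of each offending
   G-run (C-run on the antisense side) and iterating to a fixpoint (bounded
   at 10 iterations; convergence is typically immediate because runs halve
   each pass). Scrubbing of imperfect classes is available through
   `scrub_classes` but is off by default: planted-recovery semantics only
   require a perfect-clean background, imperfect motifs on random sequence
   are roughly an order of magnitude denser, and every planted motif is
   insulated anyway (next point).
2. **Guard zones**: every planted motif is wrapped in 13 bp of non-G/non-C
   bases on both sides — longer than the longest allowed loop (12 bp) — so
   planted motifs can neither extend into the background nor chain with it,
   and recovery at exact truth coordinates is well-defined.
3. **Genes**: laid on a per-chromosome slot grid with a 6-kb clearance so
   ±5-kb profile windows never cross slots; exon/intron structure is
   sampled (first exon ≥ 300 bp so the peak2 window `[0,250)` and the
   intron-1 peak3 zone are disjoint on the gene axis; introns ≥ 150 bp).
   CDS blocks equal exon blocks — UTR-less models, as in the
   high-confidence annotations this emulates.
4. **Planted features**: motif sequences per class are minimal instances
   (15-bp perfect, 31-bp 8-stem multimeric, 17-bp single-bulge imperfect,
   26-bp long-loop imperfect) so zone arithmetic is exact. TE intervals are
   annotation-only labels (no sequence content). SNPs are planted in stem,
   loop, flank or intergenic zones with reference alleles read back from
   the emitted sequence. GO terms are assigned independently of G4 status —
   a null annotation, so association tests should be uniform.

Everything is deterministic under the spec seed, and the truth ledger
(motifs with class/zone/host gene, genes, TEs, SNPs, GO map) is returned
alongside the sequence and written as plain text by `write_synthetic()`.

What the generator does *not* emulate: real base-composition heterogeneity
(isochores, CpG/TE landscapes), motif length and loop-length diversity,
overlapping gene models, alternative transcripts, UTR annotation, or TE
sequence content. Passing the planted-recovery tests therefore demonstrates
correctness of the interval bookkeeping and scanners under controlled
conditions, not biological realism of any particular density value.

## Problem sizes used by the tests and the acceptance script

Oracle equivalence runs on 200 random 2-kb sequences (perfect, both
strands) and 100 random 500-bp sequences (imperfect, post-merge); planted
recovery and profiling run on a 10-Mb, 500-gene cohort with peak planting
probabilities (0.6, 0.3, 0.1); the smoothing comparison uses a 2-Mb,
100-gene bimodal cohort (peak1 = peak2 = 1); enrichment calibration uses
5,000 motifs against 500 2-kb regions on 10 Mb with 50 shuffle replicates;
the random-background density uses three 10-Mb iid datasets; the GO null
uses 2,000 random terms over a 3,000-gene universe. These sizes give
sampling errors well inside the tolerances asserted while keeping the whole
suite runnable on a laptop.

## Known limitations

* No thermodynamic or structural scoring (G4Hunter-style), no RNA G4
  folding, no experimental G4-seq integration.
* Imperfect scanning does not model mismatched (substituted) stems,
  two-quartet (G2) motifs, or multimer linking of bulged stems.
* The `n_stems` of a merged imperfect motif is the longest chain over its
  candidates, which is a lower bound on what a structure-aware enumeration
  might assign.
* A merged imperfect motif count is not monotone in the loop bound in
  pathological cases (a longer loop can fuse two previously separate
  motifs); coverage, however, is monotone, and both are exercised in the
  tests.
* Shuffling has no exclusion zones (gaps, chrUn), matching the plain
  interval-shuffle convention.
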