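# g4tools

Genome-wide discovery and distribution analysis of putative G-quadruplex
(G4) motifs, for plant (and other) genomes.

G-quadruplexes are four-stranded nucleic-acid structures formed by stacked
planar quartets of guanines, implicated in transcription, replication,
splicing and genome stability. In large cereal genomes, predicted G4 motifs
concentrate on the gene-antisense strand immediately upstream of the start
codon, in the first coding exon, and at the first intron's start — a
pattern that coarse smoothing windows blur into a single peak. `g4tools`
implements the complete sequence-based pipeline for this kind of study:

* **Motif scanning** with the quadparser-style perfect pattern
  (G<sub>3+</sub>L<sub>1–7</sub>)<sub>3+</sub>G<sub>3+</sub>, multimeric
  variants with ≥ 8 G-stems, and bulged imperfect motifs (stems of 3–4 Gs
  with ≤ 1 bulge of ≤ 2 non-G bases; loops ≤ 7 or ≤ 12 bp), on both
  strands, with leftmost greedy non-overlapping semantics and BED-style
  0-based half-open coordinates.
* **Gene-feature assignment** from GFF3: 1-kb upstream/downstream windows,
  500-bp UTR-proxy flanks, gene bodies, first-vs-rest CDS and intron
  blocks; TE overlap tallies; SNP-in-motif location and stem-disruption
  classification by mutate-and-rescan.
* **Distribution statistics**: per-feature densities (motifs per Mb of
  unioned span), metagene positional profiles anchored at the start codon
  or first intron with moving-average smoothing, peak gene sets, and
  fixed-bin per-chromosome histograms (Circos track input).
* **Enrichment**: interval shuffling against the genome, fold enrichment
  of motifs in genic regions, median-of-three iid random backgrounds,
  per-term Pearson chi-square GO association and hypergeometric GO
  enrichment with Benjamini–Hochberg correction.
* **A synthetic genome generator** (`generate()`,
  `plant_profile_cohort()`) that emits FASTA/GFF3/BED/TSV plus a truth
  ledger of planted motifs, genes, TEs and SNPs, so the entire pipeline is
  testable end-to-end without downloading a genome.

## Worked example

Build a small synthetic cohort with motifs planted on the antisense strand
at the three peak zones, scan it, and profile it:

```r
library(g4tools)

spec <- synthetic_spec(chrom_lengths = c(chr1 = 4e5), n_genes = 20L,
                       multi_exon_fraction = 1, seed = 11L)
sg <- plant_profile_cohort(spec, p_peak1 = 0.7, p_peak2 = 0.4, p_peak3 = 0.2)

motifs <- scan_genome(sg$genome, "perfect")
head(motifs[, c("chrom", "start", "end", "strand", "n_stems")], 3)
#>   chrom start   end strand n_stems
#> 1 chr1   9310  9325 +            4
#> 2 chr1  32333 32348 +            4
#> 3 chr1  48013 48028 -            4

prof <- positional_frequency(motifs, sg$genes, "start_codon")
v <- profile_values(prof, "fraction")
v$offset[which.max(v$antisense)]   # -250: the 5'-UTR-side peak
max(v$antisense)                   # 0.75: fraction of genes covered there

peaks <- peak_gene_sets(motifs, sg$genes)
lengths(peaks)
#> peak1 peak2 peak3
#>    15     7     2

g4_density(motifs, tibble::tibble(chrom = "chr1", start = 0L, end = 400000L))
#>   feature_class n_motifs span_bp density_per_Mb
#>          region       24   4e+05             60
```

The 24 scanned motifs are exactly the planted ones (the background is
scrubbed of spurious perfect motifs), the antisense profile peaks at offset
−250 with 75% of genes covered (close to the planting probability 0.7 plus
boundary-spanning peak plants), and the three peak gene sets match the
Bernoulli draws recorded in the truth ledger `sg$motifs`.

A thin command-line wrapper for plain FASTA→BED scanning ships in
`inst/scripts/g4scan.R`:

```sh
Rscript inst/scripts/g4scan.R --fasta genome.fa --mode perfect --out motifs.bed
```

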