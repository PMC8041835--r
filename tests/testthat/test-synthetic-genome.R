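# Synthetic genome generation: scrubbing, planting, truth-ledger round trips.

small_spec <- function(...) {
  synthetic_spec(chrom_lengths = c(chrA = 150000, chrB = 100000),
                 n_genes = 10L, seed = 123L, ...)
}

test_that("generation is deterministic under the seed", {
  spec <- small_spec(motif_placements = motif_placement("perfect", "peak1"),
                     te_density = 0.05,
                     snp_plan = c(stem = 2L, loop = 2L, intergenic = 3L),
                     go_n_terms = 5L)
  a <- generate(spec)
  b <- generate(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$motifs, b$motifs)
  expect_identical(a$genes, b$genes)
  expect_identical(a$snps, b$snps)
})

test_that("scrubbed background contains no perfect motif on either strand", {
  sg <- generate(small_spec())
  expect_equal(nrow(scan_genome(sg$genome, "perfect")), 0L)
  expect_lte(sg$scrub_iterations, 10L)
})

test_that("imperfect scrubbing empties the background of bulged motifs too", {
  spec <- synthetic_spec(chrom_lengths = c(c = 40000), n_genes = 0L,
                         seed = 77L)
  sg <- generate(spec, scrub_classes = c("perfect", "imperfect",
                                         "imperfect_long"))
  expect_equal(nrow(scan_genome_imperfect(sg$genome,
                                          imperfect_params(max_loop = 7))), 0L)
  expect_equal(nrow(scan_genome_imperfect(sg$genome,
                                          imperfect_params(max_loop = 12))), 0L)
})

test_that("planted motifs of every class are recovered exactly at truth coordinates", {
  spec <- small_spec(motif_placements = dplyr::bind_rows(
    motif_placement("perfect", "uniform", count = 25L),
    motif_placement("multimeric", "uniform", count = 5L),
    motif_placement("imperfect", "uniform", count = 8L),
    motif_placement("imperfect_long", "uniform", count = 8L)))
  sg <- generate(spec)
  truth <- sg$motifs
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$strand))

  scanned_p <- scan_genome(sg$genome, "perfect")
  expect_equal(key(scanned_p[scanned_p$n_stems < 8, ]),
               key(truth[truth$motif_class == "perfect", ]))

  # exactly the 5 planted multimeric arrays
  scanned_m <- scan_genome(sg$genome, "multimeric")
  expect_equal(key(scanned_m), key(truth[truth$motif_class == "multimeric", ]))

  imp <- scan_genome_imperfect(sg$genome, imperfect_params(max_loop = 7))
  for (i in which(truth$motif_class == "imperfect")) {
    expect_true(any(imp$chrom == truth$chrom[i] &
                      imp$start == truth$start[i] &
                      imp$end == truth$end[i] &
                      imp$strand == truth$strand[i]))
  }
  impl <- scan_genome_imperfect(sg$genome, imperfect_params(max_loop = 12))
  for (i in which(truth$motif_class == "imperfect_long")) {
    expect_true(any(impl$chrom == truth$chrom[i] &
                      impl$start == truth$start[i] &
                      impl$end == truth$end[i] &
                      impl$strand == truth$strand[i]))
  }
})

test_that("a zero-placement spec scans clean and the GFF3 round-trips", {
  sg <- generate(small_spec(te_density = 0.03, go_n_terms = 4L))
  expect_equal(nrow(scan_genome(sg$genome, "perfect")), 0L)

  dir <- withr::local_tempdir()
  write_synthetic(sg, dir)
  genes2 <- read_genes(file.path(dir, "genes.gff3"))
  expect_equal(genes2$gene_id, sg$genes$gene_id)
  expect_equal(genes2$start, sg$genes$start)
  expect_equal(genes2$end, sg$genes$end)
  expect_equal(genes2$strand, sg$genes$strand)
  expect_equal(genes2$n_exons, sg$genes$n_exons)
  expect_equal(genes2$cds_blocks, sg$genes$cds_blocks)
  expect_equal(genes2$exon_blocks, sg$genes$exon_blocks)
  expect_equal(genes2$confidence, sg$genes$confidence)

  genome2 <- read_genome_fasta(file.path(dir, "genome.fasta"))
  expect_equal(genome2, unlist(sg$genome))

  snps2 <- read_snps(file.path(dir, "snps.tsv"))
  expect_equal(snps2$pos, sg$snps$pos)

  tes2 <- read_tes(file.path(dir, "tes.bed"))
  expect_equal(tes2$start, sg$tes$start)
})

test_that("gene-zone planting lands where feature assignment expects", {
  spec <- small_spec(multi_exon_fraction = 1,
                     motif_placements = dplyr::bind_rows(
                       motif_placement("perfect", "peak1", prob = 1),
                       motif_placement("perfect", "peak2", prob = 1),
                       motif_placement("perfect", "peak3", prob = 1),
                       motif_placement("perfect", "cds_rest", prob = 1)))
  sg <- generate(spec)
  m <- scan_genome(sg$genome, "perfect")
  expect_equal(nrow(m), nrow(sg$motifs))
  asg <- assign_motifs(m, sg$genes)
  truth <- sg$motifs
  truth$motif_id <- sprintf("perfect:%s:%d-%d:%s", truth$chrom, truth$start,
                            truth$end, truth$strand)
  for (zone in c("peak1", "peak2", "peak3", "cds_rest")) {
    ids <- truth$motif_id[truth$zone == zone]
    want_cat <- c(peak1 = "upstream_1k", peak2 = "cds_first",
                  peak3 = "intron_first", cds_rest = "cds_rest")[[zone]]
    for (id in ids) {
      expect_true(want_cat %in% asg$category[asg$motif_id == id],
                  label = sprintf("%s assigned %s", id, want_cat))
    }
  }
  # peak plants are antisense relative to their host gene
  expect_true(all(asg$relation[asg$motif_id %in%
                                 truth$motif_id[truth$zone == "peak1"]] ==
                    "antisense"))
})

test_that("planted SNP zones agree with disruption classification", {
  spec <- small_spec(motif_placements = motif_placement("perfect", "uniform",
                                                        count = 12L),
                     snp_plan = c(stem = 4L, loop = 4L, flank = 4L,
                                  intergenic = 4L))
  sg <- generate(spec)
  m <- scan_genome(sg$genome, "perfect")
  hits <- snps_in_motifs(m, sg$snps)
  # stem and loop SNPs fall inside motifs, flank and intergenic outside
  expect_setequal(hits$marker_id,
                  sg$snps$marker_id[sg$snps$zone %in% c("stem", "loop")])
  for (i in seq_len(nrow(sg$snps))) {
    snp <- sg$snps[i, ]
    if (snp$zone == "intergenic") next
    motif <- m[m$motif_id == snp$motif_id, ]
    cls <- classify_snp_disruption(motif, snp, sg$genome)
    want <- c(stem = "stem_disruptive", loop = "loop_or_flank",
              flank = "loop_or_flank")[[snp$zone]]
    expect_equal(cls, want, info = snp$marker_id)
  }
  # the genome base at each SNP equals the recorded reference allele
  for (i in seq_len(nrow(sg$snps))) {
    expect_equal(substring(sg$genome[[sg$snps$chrom[i]]],
                           sg$snps$pos[i] + 1, sg$snps$pos[i] + 1),
                 sg$snps$ref[i])
  }
})

test_that("profile cohort planting respects probabilities and peak recovery", {
  spec <- synthetic_spec(chrom_lengths = c(c1 = 400000), n_genes = 25L,
                         multi_exon_fraction = 1, seed = 31L)
  sg <- plant_profile_cohort(spec, p_peak1 = 1, p_peak2 = 0, p_peak3 = 0)
  m <- scan_genome(sg$genome, "perfect")
  ps <- peak_gene_sets(m, sg$genes)
  expect_setequal(ps$peak1, sg$genes$gene_id)
  expect_equal(ps$peak2, character(0))
  expect_equal(ps$peak3, character(0))

  sg0 <- plant_profile_cohort(spec, p_peak1 = 0, p_peak2 = 0, p_peak3 = 0)
  m0 <- scan_genome(sg0$genome, "perfect")
  expect_equal(nrow(m0), 0L)
  ps0 <- peak_gene_sets(m0, sg0$genes)
  expect_equal(lengths(ps0), c(peak1 = 0L, peak2 = 0L, peak3 = 0L))
})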