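# GFF3 / table readers, feature assignment, TE and SNP overlap, disruption.

write_fixture_gff3 <- function(path) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t300\t.\t+\t.\tID=gA;primary_confidence_class=HC",
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\ttest\tCDS\t1\t100\t.\t+\t.\tID=gA.1.c1;Parent=gA.1",
    "chr1\ttest\tCDS\t201\t300\t.\t+\t.\tID=gA.1.c2;Parent=gA.1",
    "chr1\ttest\tgene\t2001\t2300\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t2001\t2300\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\texon\t2001\t2100\t.\t-\t.\tID=gB.1.e2;Parent=gB.1",
    "chr1\ttest\texon\t2201\t2300\t.\t-\t.\tID=gB.1.e1;Parent=gB.1",
    "chr1\ttest\tCDS\t2001\t2100\t.\t-\t.\tID=gB.1.c2;Parent=gB.1",
    "chr1\ttest\tCDS\t2201\t2300\t.\t-\t.\tID=gB.1.c1;Parent=gB.1")
  writeLines(lines, path)
  path
}

test_that("GFF3 gene models convert to 0-based half-open, transcription order", {
  path <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  genes <- read_genes(path)
  expect_equal(nrow(genes), 2L)
  gA <- genes[genes$gene_id == "gA", ]
  expect_equal(c(gA$start, gA$end), c(0L, 300L))
  expect_equal(gA$confidence, "HC")
  expect_equal(gA$cds_blocks[[1]][, "start"], c(0L, 200L), ignore_attr = TRUE)
  # minus-strand blocks come out 5'->3' of the gene (descending genomic)
  gB <- genes[genes$gene_id == "gB", ]
  expect_equal(gB$cds_blocks[[1]][, "start"], c(2200L, 2000L),
               ignore_attr = TRUE)
  expect_equal(gB$n_exons, 2L)
})

test_that("children without a known parent are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e;Parent=g1.1",
    "chr1\tt\tCDS\t1\t100\t.\t+\t.\tID=c;Parent=ghost.1"), path)
  expect_warning(genes <- read_genes(path), "without a known parent")
  expect_false(genes$has_cds[1])
  expect_equal(genes$n_exons[1], 1L)
})

fake_motif <- function(chrom, start, end, strand = "+", class = "perfect") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, motif_class = class,
                 n_stems = 4L, motif_seq = NA_character_,
                 motif_id = sprintf("%s:%s:%d-%d:%s", class, chrom, start,
                                    end, strand))
}

test_that("motifs are assigned to every overlapping category", {
  path <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  genes <- read_genes(path)
  # upstream window of gB ("-" gene): genomic [2300, 3300); its 500-bp 5'
  # flank is [2300, 2800)
  m <- rbind(
    fake_motif("chr1", 2310L, 2330L),        # 5' flank of gB
    fake_motif("chr1", 220L, 240L),          # inside second CDS of gA
    fake_motif("chr1", 50L, 60L),            # inside first CDS of gA
    fake_motif("chr1", 120L, 140L))          # intron 1 of gA
  asg <- assign_motifs(m, genes)
  catset <- function(id, gene) sort(asg$category[asg$motif_id == id &
                                                   asg$gene_id == gene])
  expect_equal(catset(m$motif_id[1], "gB"),
               c("flank5_500", "upstream_1k"))
  expect_equal(catset(m$motif_id[2], "gA"), c("cds_rest", "gene_body"))
  expect_equal(catset(m$motif_id[3], "gA"), c("cds_first", "gene_body"))
  expect_equal(catset(m$motif_id[4], "gA"), c("gene_body", "intron_first"))
  # gene-relative strand recorded against the gene
  expect_equal(unique(asg$relation[asg$gene_id == "gB"]), "antisense")
  expect_equal(unique(asg$relation[asg$gene_id == "gA"]), "sense")
})

test_that("assignments agree with a naive all-pairs overlap check", {
  set.seed(71)
  path <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  genes <- read_genes(path)
  starts <- sort(sample(0:3500, 40))
  m <- fake_motif("chr1", starts, starts + 15L,
                  strand = sample(c("+", "-"), 40, replace = TRUE))
  asg <- assign_motifs(m, genes)
  cats <- dplyr::bind_rows(lapply(1:2, function(i)
    g4tools:::gene_category_intervals(genes[i, ])))
  naive <- naive_overlaps(m, cats)
  naive_keys <- sort(unique(paste(m$motif_id[naive$qi], cats$gene_id[naive$si],
                                  cats$category[naive$si])))
  # apply the first/rest exclusivity rule to the naive result too
  drop_rule <- function(keys, first, rest) {
    pg <- sub(paste0(" ", first, "$"), "", keys[grepl(paste0(" ", first, "$"), keys)])
    keys[!(grepl(paste0(" ", rest, "$"), keys) &
             sub(paste0(" ", rest, "$"), "", keys) %in% pg)]
  }
  naive_keys <- drop_rule(naive_keys, "cds_first", "cds_rest")
  naive_keys <- drop_rule(naive_keys, "intron_first", "intron_rest")
  got_keys <- sort(paste(asg$motif_id, asg$gene_id, asg$category))
  expect_equal(got_keys, naive_keys)
})

test_that("gene G4 flags are monotone in flank size", {
  path <- write_fixture_gff3(withr::local_tempfile(fileext = ".gff3"))
  genes <- read_genes(path)
  m <- fake_motif("chr1", c(400L, 1200L, 2500L), c(415L, 1215L, 2515L))
  n <- vapply(c(0L, 200L, 500L, 1000L),
              function(f) sum(genes_with_g4(m, genes, flank = f)$has_g4),
              numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("TE overlap counts each motif once and tallies families", {
  m <- rbind(fake_motif("c", 100L, 120L), fake_motif("c", 500L, 520L))
  expect_equal(overlap_tes(m, tibble::tibble(chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             family = character())),
               list(n_in_te = 0L, fraction = 0, per_family = integer()))
  tes <- tibble::tibble(chrom = "c", start = c(100L, 90L, 505L),
                        end = c(120L, 130L, 515L),
                        family = c("RLX", "RLX", "RLG"))
  res <- overlap_tes(m, tes)
  expect_equal(res$n_in_te, 2L)       # nested TEs count the motif once
  expect_equal(res$fraction, 1.0)
  expect_equal(res$per_family[["RLX"]], 1L)
  expect_equal(res$per_family[["RLG"]], 1L)
})

test_that("SNP-in-motif uses half-open boundaries", {
  m <- fake_motif("c", 100L, 115L)
  snps <- tibble::tibble(marker_id = c("s1", "s2", "s3"), chrom = "c",
                         pos = c(100L, 114L, 115L), ref = "G", alt = "A")
  hit <- snps_in_motifs(m, snps)
  expect_equal(hit$marker_id, c("s1", "s2"))
  expect_equal(hit$offset_in_motif, c(0L, 14L))
})

test_that("SNP disruption classification follows the stem parse and rescan", {
  chrom <- paste0(strrep("T", 20), "GGGAGGGTGGGAGGG", strrep("T", 20))
  genome <- list(chr = chrom)
  motif <- scan_both_strands(chrom, id = "chr")[1, ]
  expect_equal(c(motif$start, motif$end), c(20L, 35L))
  snp <- function(pos, ref, alt) tibble::tibble(marker_id = "s", chrom = "chr",
                                                pos = pos, ref = ref, alt = alt)
  # middle G of stem 2 -> A: no 4-run motif survives
  expect_equal(classify_snp_disruption(motif, snp(25L, "G", "A"), genome),
               "stem_disruptive")
  # single-base loop of the minimal motif
  expect_equal(classify_snp_disruption(motif, snp(23L, "A", "C"), genome),
               "loop_or_flank")
  # flank position
  expect_equal(classify_snp_disruption(motif, snp(40L, "T", "C"), genome),
               "loop_or_flank")
  expect_error(classify_snp_disruption(motif, snp(60L, "T", "C"), genome),
               "outside")
  # a 4-G first run slides to 3: tolerated
  chrom2 <- paste0(strrep("T", 20), "GGGGAGGGTGGGAGGG", strrep("T", 20))
  genome2 <- list(chr = chrom2)
  motif2 <- scan_both_strands(chrom2, id = "chr")[1, ]
  expect_equal(classify_snp_disruption(motif2, snp(20L, "G", "A"), genome2),
               "stem_tolerated")
  # ref == alt is never disruptive
  expect_false(classify_snp_disruption(motif, snp(25L, "G", "G"), genome) ==
                 "stem_disruptive")
})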