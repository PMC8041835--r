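## Seeded synthetic genomes with planted G4 motifs and a truth ledger.
##
## The generator draws an iid background at a target GC content, scrubs it of
## spurious perfect G4 motifs (both strands) to a fixpoint, lays out
## non-overlapping gene models on a slot grid, then writes motif sequences of
## each class at gene-relative offsets (or uniformly), each wrapped in 13-bp
## non-G/non-C guard zones so planted motifs can neither extend nor chain
## into the background (13 bp exceeds the longest allowed loop of 12 bp).
## Everything is deterministic under the spec seed.

PLANT_SEQS <- list(
  perfect = "GGGAGGGTGGGAGGG",                                   # 15 bp, 4 stems
  multimeric = paste0(strrep("GGGA", 7), "GGG"),                 # 31 bp, 8 stems
  imperfect = "GGAGGTGGGTGGGTGGG",                               # 17 bp, bulged stem
  imperfect_long = "GGAGGTGGGAAAAAAAAATGGGTGGG"                  # 26 bp, 10-bp loop
)

GUARD <- 13L

#' Describe one motif planting rule
#'
#' @param motif_class One of `perfect`, `multimeric`, `imperfect`,
#'   `imperfect_long`.
#' @param zone Placement zone: `"offset"` (explicit gene-relative offset),
#'   `"peak1"` (-250), `"peak2"` (+125), `"peak3"` (first intron start + 10,
#'   multi-exon genes only), `"cds_first"` (+30), `"cds_rest"` (second exon
#'   start + 10, multi-exon only), or `"uniform"` (uniform genomic
#'   placement, `count` motifs).
#' @param offset Gene-relative offset of the motif 5' end for
#'   `zone = "offset"`.
#' @param strand Gene-relative strand, `"antisense"` or `"sense"` (ignored
#'   for `"uniform"`, where the absolute strand is drawn at random).
#' @param prob Per-gene Bernoulli planting probability (gene zones).
#' @param count Number of motifs (`zone = "uniform"` only).
#' @return One-row placement tibble.
#' @export
motif_placement <- function(motif_class = "perfect",
                            zone = c("offset", "peak1", "peak2", "peak3",
                                     "cds_first", "cds_rest", "uniform"),
                            offset = NA_integer_,
                            strand = c("antisense", "sense"),
                            prob = 1, count = NA_integer_) {
  zone <- match.arg(zone)
  strand <- match.arg(strand)
  stopifnot(motif_class %in% names(PLANT_SEQS))
  if (zone == "offset") stopifnot(!is.na(offset))
  if (zone == "uniform") stopifnot(!is.na(count))
  tibble::tibble(motif_class = motif_class, zone = zone,
                 offset = as.integer(offset), strand = strand,
                 prob = prob, count = as.integer(count))
}

#' Specification for a synthetic genome
#'
#' @param chrom_lengths Named (or unnamed, then auto-named) numeric vector of
#'   chromosome lengths in bp.
#' @param gc_content Background GC fraction in (0, 1); default 0.44,
#'   a typical Triticeae-like genome-wide value.
#' @param n_genes Total genes, distributed across chromosomes in proportion
#'   to length.
#' @param multi_exon_fraction Fraction of genes with >= 2 exons; default
#'   0.69 (the multi-exon share of the barley high-confidence gene set).
#' @param motif_placements Tibble of [motif_placement()] rows (may be
#'   `NULL`).
#' @param te_density Target fraction of the genome covered by planted TE
#'   intervals (annotation only; the sequence is untouched).
#' @param snp_plan Named counts of SNPs to plant per zone:
#'   `stem`, `loop`, `flank`, `intergenic`.
#' @param go_n_terms,go_term_size Number of GO terms and the (min, max) genes
#'   per term, assigned independently of G4 status (a null annotation).
#' @param seed Integer seed; the whole generation is deterministic under it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(chrom_lengths, gc_content = 0.44, n_genes = 50L,
                           multi_exon_fraction = 0.69,
                           motif_placements = NULL, te_density = 0,
                           snp_plan = c(stem = 0L, loop = 0L, flank = 0L,
                                        intergenic = 0L),
                           go_n_terms = 0L, go_term_size = c(10L, 50L),
                           seed = 1L) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  plan <- c(stem = 0L, loop = 0L, flank = 0L, intergenic = 0L)
  plan[names(snp_plan)] <- as.integer(snp_plan)
  spec <- list(chrom_lengths = chrom_lengths, gc_content = gc_content,
               n_genes = as.integer(n_genes),
               multi_exon_fraction = multi_exon_fraction,
               motif_placements = motif_placements,
               te_density = te_density, snp_plan = plan,
               go_n_terms = as.integer(go_n_terms),
               go_term_size = as.integer(go_term_size),
               seed = as.integer(seed))
  stopifnot(gc_content > 0, gc_content < 1,
            multi_exon_fraction >= 0, multi_exon_fraction <= 1,
            te_density >= 0, te_density < 1,
            all(chrom_lengths >= 1000))
  class(spec) <- "synthetic_spec"
  spec
}

random_background <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

## Break every offending run inside motif spans by mutating its middle base.
## 'motifs' is a scan result; runs of `base` with length >= min_run within
## each span are broken (G -> T on "+", C -> A on "-"). Returns midpoint
## positions (1-based) to mutate, per chromosome name.
scrub_positions <- function(genome, motifs, min_run = 3L) {
  pos <- list()
  for (ch in unique(motifs$chrom)) {
    mm <- motifs[motifs$chrom == ch, , drop = FALSE]
    for (base in c("G", "C")) {
      sel <- mm$strand == (if (base == "G") "+" else "-")
      if (!any(sel)) next
      spans <- mm[sel, , drop = FALSE]
      hits <- integer(0)
      for (i in seq_len(nrow(spans))) {
        sub <- substring(genome[[ch]], spans$start[i] + 1L, spans$end[i])
        m <- gregexpr(sprintf("%s{%d,}", base, min_run), sub)[[1]]
        if (m[1] == -1L) next
        mid <- as.integer(m) + attr(m, "match.length") %/% 2L
        hits <- c(hits, spans$start[i] + mid)  # 1-based genomic
      }
      key <- paste0(ch, ":", base)
      pos[[key]] <- c(pos[[key]], hits)
    }
  }
  pos
}

apply_mutations <- function(genome, pos) {
  for (key in names(pos)) {
    if (!length(pos[[key]])) next
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    ch <- parts[1]; base <- parts[2]
    chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    chars[unique(pos[[key]])] <- if (base == "G") "T" else "A"
    genome[[ch]] <- paste(chars, collapse = "")
  }
  genome
}

scrub_genome <- function(genome, scrub_classes, max_iter = 10L) {
  iters <- 0L
  for (it in seq_len(max_iter)) {
    found <- list()
    if ("perfect" %in% scrub_classes) {
      found$perfect <- scan_genome(genome, "perfect")
    }
    if ("imperfect" %in% scrub_classes) {
      found$imp <- scan_genome_imperfect(genome, imperfect_params(max_loop = 7L))
    }
    if ("imperfect_long" %in% scrub_classes) {
      found$impl <- scan_genome_imperfect(genome, imperfect_params(max_loop = 12L))
    }
    motifs <- dplyr::bind_rows(found)
    if (nrow(motifs) == 0L) return(list(genome = genome, iterations = iters))
    min_run <- if (any(c("imperfect", "imperfect_long") %in% scrub_classes))
      2L else 3L
    genome <- apply_mutations(genome, scrub_positions(genome, motifs, min_run))
    iters <- it
  }
  # verify fixpoint after the final pass
  left <- sum(vapply(scrub_classes, function(cl) {
    n <- switch(cl,
                perfect = nrow(scan_genome(genome, "perfect")),
                imperfect = nrow(scan_genome_imperfect(
                  genome, imperfect_params(max_loop = 7L))),
                imperfect_long = nrow(scan_genome_imperfect(
                  genome, imperfect_params(max_loop = 12L))))
    as.numeric(n)
  }, numeric(1)))
  if (left > 0) stop("background scrub did not converge in 10 iterations",
                     call. = FALSE)
  list(genome = genome, iterations = iters)
}

empty_genes <- function() {
  tibble::tibble(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 confidence = character(), has_cds = logical(),
                 n_exons = integer(), cds_blocks = list(),
                 exon_blocks = list())
}

## Sample gene structures and lay genes on a per-chromosome slot grid.
## The margin keeps every gene (and its planted motifs and +/-5 kb profile
## window) clear of slot and chromosome boundaries.
sample_genes <- function(spec, margin = 6000L) {
  if (spec$n_genes <= 0L) return(empty_genes())
  chl <- spec$chrom_lengths
  n_per <- pmax(0L, as.integer(round(spec$n_genes * chl / sum(chl))))
  # fix rounding so totals match
  while (sum(n_per) > spec$n_genes) n_per[which.max(n_per)] <-
      n_per[which.max(n_per)] - 1L
  while (sum(n_per) < spec$n_genes) n_per[which.max(chl / (n_per + 1))] <-
      n_per[which.max(chl / (n_per + 1))] + 1L
  rows <- list()
  gidx <- 0L
  for (ci in seq_along(chl)) {
    n_i <- n_per[ci]
    if (n_i == 0L) next
    L <- as.integer(chl[ci])
    slot <- L %/% n_i
    for (k in seq_len(n_i)) {
      gidx <- gidx + 1L
      multi <- stats::runif(1) < spec$multi_exon_fraction
      n_exons <- if (multi) sample(2:4, 1L) else 1L
      # transcription order: the first exon is kept >= 300 bp so peak2 /
      # first-CDS plants fit inside it and the peak3 zone (intron 1 start)
      # stays disjoint from the [0, 250) peak2 window on the gene axis
      tx_exon_lens <- c(sample(300:400, 1L),
                        if (n_exons > 1L) sample(150:400, n_exons - 1L,
                                                 replace = TRUE))
      intron_lens <- if (n_exons > 1L) sample(150:800, n_exons - 1L,
                                              replace = TRUE) else integer(0)
      glen <- sum(tx_exon_lens) + sum(intron_lens)
      avail <- slot - 2L * margin - glen
      if (avail < 1L) {
        stop("infeasible packing: chromosome slots too small for genes",
             call. = FALSE)
      }
      gstart <- (k - 1L) * slot + margin + sample.int(avail, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      # genomic (ascending) construction order
      exon_lens <- if (strand == "+") tx_exon_lens else rev(tx_exon_lens)
      b_start <- gstart + cumsum(c(0L, head_int(exon_lens + c(intron_lens, 0L),
                                                n_exons - 1L)))
      blocks <- cbind(start = as.integer(b_start),
                      end = as.integer(b_start + exon_lens))
      if (strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), ,
                                          drop = FALSE]
      rows[[gidx]] <- tibble::tibble(
        gene_id = sprintf("SYNG%04d", gidx),
        chrom = names(chl)[ci], strand = strand,
        start = as.integer(gstart), end = as.integer(gstart + glen),
        confidence = "HC", has_cds = TRUE, n_exons = as.integer(n_exons),
        cds_blocks = list(blocks), exon_blocks = list(blocks))
    }
  }
  dplyr::bind_rows(rows)
}

head_int <- function(x, n) if (n <= 0L) integer(0) else x[seq_len(n)]

## Gene-axis offset of a zone's motif 5' end, or NA if the gene is not
## eligible. exon lengths are in transcription order.
zone_axis_offset <- function(gene, zone, offset) {
  exon <- gene$exon_blocks[[1]]
  exon_lens <- abs(exon[, 2L] - exon[, 1L])
  switch(zone,
         offset = offset,
         peak1 = -250L,
         peak2 = 125L,
         peak3 = if (gene$n_exons >= 2L) exon_lens[1L] + 10L else NA_integer_,
         cds_first = 30L,
         cds_rest = if (gene$n_exons >= 2L) {
           intron1 <- if (gene$strand == "+")
             gene$exon_blocks[[1]][2L, 1L] - gene$exon_blocks[[1]][1L, 2L]
           else gene$exon_blocks[[1]][1L, 1L] - gene$exon_blocks[[1]][2L, 2L]
           exon_lens[1L] + intron1 + 10L
         } else NA_integer_)
}

#' Generate a synthetic genome with planted features
#'
#' See [synthetic_spec()] for the knobs. Planted motif coordinates, gene
#' models, TEs and SNPs are returned as a truth ledger alongside the
#' sequence; re-running with the same spec gives byte-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @param scrub_classes Motif classes removed from the background before
#'   planting; default `"perfect"` (add `"imperfect"` / `"imperfect_long"`
#'   when spurious bulged motifs would matter for the downstream analysis).
#' @param gene_margin Clearance in bp between a gene and its slot /
#'   chromosome boundaries (default 6000, enough for the +/-5 kb profile
#'   windows).
#' @return A `synthetic_genome` list: `genome` (named character), `genes`,
#'   `motifs` (truth ledger with absolute strand, class, host gene and
#'   zone), `tes`, `snps`, `go`, `spec`, `scrub_iterations`.
#' @export
generate <- function(spec, scrub_classes = "perfect", gene_margin = 6000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genome <- lapply(spec$chrom_lengths, function(L) {
    random_background(as.integer(L), spec$gc_content)
  })
  names(genome) <- names(spec$chrom_lengths)
  sc <- scrub_genome(genome, scrub_classes)
  genome <- sc$genome

  genes <- sample_genes(spec, margin = as.integer(gene_margin))

  reserved <- list()  # per chrom: matrix of reserved [start, end) incl guards
  truth <- list()
  plant_one <- function(genome, chrom, gs, seq, strand_abs, cls, host, zone,
                        rel) {
    len <- nchar(seq)
    L <- nchar(genome[[chrom]])
    lo <- gs - GUARD
    hi <- gs + len + GUARD
    if (lo < 0L || hi > L) return(list(genome = genome, ok = FALSE))
    res <- reserved[[chrom]]
    if (!is.null(res) && any(res[, 1L] < hi & res[, 2L] > lo)) {
      return(list(genome = genome, ok = FALSE))
    }
    guard_n <- hi - lo - len
    guard_chars <- sample(c("A", "T"), guard_n, replace = TRUE)
    written <- if (strand_abs == "-") revcomp(seq) else seq
    chars <- c(guard_chars[seq_len(GUARD)],
               strsplit(written, "", fixed = TRUE)[[1]],
               guard_chars[(GUARD + 1L):guard_n])
    genome[[chrom]] <- paste0(substring(genome[[chrom]], 1L, lo),
                              paste(chars, collapse = ""),
                              substring(genome[[chrom]], hi + 1L, L))
    reserved[[chrom]] <<- rbind(res, c(lo, hi))
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      chrom = chrom, start = as.integer(gs), end = as.integer(gs + len),
      strand = strand_abs, motif_class = cls, host_gene = host, zone = zone,
      gene_rel_strand = rel)
    list(genome = genome, ok = TRUE)
  }

  placements <- spec$motif_placements
  if (!is.null(placements) && nrow(placements)) {
    for (p in seq_len(nrow(placements))) {
      pl <- placements[p, ]
      seq <- PLANT_SEQS[[pl$motif_class]]
      if (pl$zone == "uniform") {
        chl <- vapply(genome, nchar, numeric(1))
        placed <- 0L
        tries <- 0L
        while (placed < pl$count && tries < pl$count * 200L) {
          tries <- tries + 1L
          ci <- sample(seq_along(chl), 1L, prob = chl)
          gs <- GUARD + sample.int(as.integer(chl[ci]) - nchar(seq) -
                                     2L * GUARD, 1L) - 1L
          strand_abs <- sample(c("+", "-"), 1L)
          r <- plant_one(genome, names(chl)[ci], gs, seq, strand_abs,
                         pl$motif_class, NA_character_, "uniform",
                         NA_character_)
          genome <- r$genome
          if (r$ok) placed <- placed + 1L
        }
        if (placed < pl$count) {
          stop("infeasible packing: could not place uniform motifs",
               call. = FALSE)
        }
      } else {
        for (gi in seq_len(nrow(genes))) {
          gene <- genes[gi, ]
          if (stats::runif(1) >= pl$prob) next
          off <- zone_axis_offset(gene, pl$zone, pl$offset)
          if (is.na(off)) next
          plus <- gene$strand == "+"
          a <- if (plus) gene$start else gene$end - 1L
          gs <- if (plus) a + off else a - off - nchar(seq) + 1L
          motif_strand <- if (pl$strand == "sense") gene$strand else
            (if (plus) "-" else "+")
          r <- plant_one(genome, gene$chrom, gs, seq, motif_strand,
                         pl$motif_class, gene$gene_id, pl$zone, pl$strand)
          genome <- r$genome
          if (!r$ok) {
            stop(sprintf(
              "infeasible packing: %s motif at %s:%d collides at gene %s",
              pl$zone, gene$chrom, gs, gene$gene_id), call. = FALSE)
          }
        }
      }
    }
  }
  motifs <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), motif_class = character(),
                   host_gene = character(), zone = character(),
                   gene_rel_strand = character())

  tes <- plant_tes(spec, genome)
  snps <- plant_snps(spec, genome, genes, motifs)
  go <- plant_go(spec, genes)

  structure(list(genome = genome, genes = genes, motifs = motifs, tes = tes,
                 snps = snps, go = go, spec = spec,
                 scrub_iterations = sc$iterations),
            class = "synthetic_genome")
}

plant_tes <- function(spec, genome) {
  chl <- vapply(genome, nchar, numeric(1))
  target <- spec$te_density * sum(chl)
  rows <- list()
  total <- 0
  fams <- c("RLX", "RLG_gypsy", "RLC_copia", "DTC_CACTA")
  while (total < target) {
    ci <- sample(seq_along(chl), 1L, prob = chl)
    len <- sample(500:3000, 1L)
    if (len > chl[ci]) next
    st <- sample.int(as.integer(chl[ci]) - len + 1L, 1L) - 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = names(chl)[ci], start = st, end = st + len,
      family = sample(fams, 1L, prob = c(0.4, 0.25, 0.2, 0.15)))
    total <- total + len
  }
  if (!length(rows)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), family = character()))
  }
  dplyr::bind_rows(rows)
}

plant_snps <- function(spec, genome, genes, motifs) {
  plan <- spec$snp_plan
  rows <- list()
  base_at <- function(ch, pos) substring(genome[[ch]], pos + 1L, pos + 1L)
  other <- function(ref, prefer) {
    if (prefer != ref) prefer else setdiff(c("A", "C", "G", "T"), ref)[1]
  }
  perf <- motifs[motifs$motif_class == "perfect", , drop = FALSE]
  take <- function(zone, n) {
    if (n <= 0L || nrow(perf) == 0L) return(NULL)
    picks <- perf[seq_len(min(n, nrow(perf))), , drop = FALSE]
    lapply(seq_len(nrow(picks)), function(i) {
      m <- picks[i, ]
      if (zone == "stem") {
        pos <- if (m$strand == "+") m$start + 5L else m$end - 6L
        ref <- base_at(m$chrom, pos)
        alt <- if (m$strand == "+") "A" else "T"  # breaks the G on the motif strand
      } else if (zone == "loop") {
        pos <- if (m$strand == "+") m$start + 3L else m$end - 4L
        ref <- base_at(m$chrom, pos)
        alt <- other(ref, "C")
      } else {  # flank
        pos <- m$end + 4L
        ref <- base_at(m$chrom, pos)
        alt <- other(ref, "C")
      }
      tibble::tibble(chrom = m$chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, zone = zone,
                     motif_id = sprintf("%s:%s:%d-%d:%s", m$motif_class,
                                        m$chrom, m$start, m$end, m$strand))
    })
  }
  rows <- c(rows, take("stem", plan[["stem"]]), take("loop", plan[["loop"]]),
            take("flank", plan[["flank"]]))
  n_int <- plan[["intergenic"]]
  if (n_int > 0L) {
    chl <- vapply(genome, nchar, numeric(1))
    placed <- 0L; tries <- 0L
    while (placed < n_int && tries < n_int * 500L) {
      tries <- tries + 1L
      ci <- sample(seq_along(chl), 1L, prob = chl)
      pos <- sample.int(as.integer(chl[ci]), 1L) - 1L
      ch <- names(chl)[ci]
      near_motif <- any(motifs$chrom == ch & motifs$start - 10L <= pos &
                          motifs$end + 10L > pos)
      near_gene <- nrow(genes) > 0L &&
        any(genes$chrom == ch & genes$start - 1000L <= pos &
              genes$end + 1000L > pos)
      if (near_motif || near_gene) next
      ref <- base_at(ch, pos)
      if (ref == "N") next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = ch, pos = as.integer(pos), ref = ref,
        alt = setdiff(c("A", "C", "G", "T"), ref)[1], zone = "intergenic",
        motif_id = NA_character_)
      placed <- placed + 1L
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(marker_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), zone = character(),
                          motif_id = character()))
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out,
                            marker_id = sprintf("SYNSNP%04d", seq_len(nrow(out))),
                            .before = 1L)
  out
}

plant_go <- function(spec, genes) {
  if (spec$go_n_terms <= 0L || nrow(genes) == 0L) {
    return(tibble::tibble(gene_id = character(), term = character()))
  }
  rows <- lapply(seq_len(spec$go_n_terms), function(t) {
    size <- sample(spec$go_term_size[1]:spec$go_term_size[2], 1L)
    size <- min(size, nrow(genes))
    tibble::tibble(gene_id = sample(genes$gene_id, size), term =
                     sprintf("GO:%07d", t))
  })
  dplyr::bind_rows(rows)
}

#' Generate a metagene-profile cohort with peak-zone planting
#'
#' Plants perfect motifs on the gene-antisense strand at the three peak
#' zones (-250 before the start codon, +125 after it, and the first 100 bp
#' of intron 1), with per-gene Bernoulli probabilities — the bimodal /
#' trimodal test substrate for positional profiling and smoothing.
#'
#' @param spec A [synthetic_spec()]; its `motif_placements` are replaced.
#' @param p_peak1,p_peak2,p_peak3 Per-gene planting probabilities.
#' @param ... Passed to [generate()].
#' @return A `synthetic_genome` whose truth ledger carries zone labels
#'   `peak1` / `peak2` / `peak3`.
#' @export
plant_profile_cohort <- function(spec, p_peak1 = 0.6, p_peak2 = 0.3,
                                 p_peak3 = 0.1, ...) {
  spec$motif_placements <- dplyr::bind_rows(
    motif_placement("perfect", "peak1", strand = "antisense", prob = p_peak1),
    motif_placement("perfect", "peak2", strand = "antisense", prob = p_peak2),
    motif_placement("perfect", "peak3", strand = "antisense", prob = p_peak3))
  generate(spec, ...)
}

#' Write a synthetic genome to standard files
#'
#' Emits `genome.fasta`, `genes.gff3`, `tes.bed`, `snps.tsv` (1-based
#' positions), `go.tsv`, and `truth_motifs.tsv`.
#'
#' @param sg A `synthetic_genome` from [generate()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(unlist(sg$genome), file.path(dir, "genome.fasta"))
  write_genes_gff3(sg$genes, file.path(dir, "genes.gff3"))
  te <- sg$tes
  utils::write.table(data.frame(te$chrom, te$start, te$end, te$family),
                     file.path(dir, "tes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  snps <- sg$snps
  utils::write.table(
    data.frame(marker_id = snps$marker_id, chrom = snps$chrom,
               pos = snps$pos + 1L, ref = snps$ref, alt = snps$alt),
    file.path(dir, "snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  go <- sg$go
  go_wide <- vapply(split(go$term, go$gene_id), paste, character(1),
                    collapse = ",")
  utils::write.table(
    data.frame(gene_id = names(go_wide), terms = unname(go_wide)),
    file.path(dir, "go.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sg$motifs),
                     file.path(dir, "truth_motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param genes Gene tibble (as produced by [read_genes()] or the
#'   generator).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    tid <- paste0(gid, ".1")
    line <- function(type, s0, e0, id, parent) {
      attrs <- sprintf("ID=%s", id)
      if (!is.na(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      if (type == "gene" && !is.na(g$confidence)) {
        attrs <- paste0(attrs, ";primary_confidence_class=", g$confidence)
      }
      sprintf("%s\tg4tools\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s0 + 1L, e0, g$strand, attrs)
    }
    out <- c(line("gene", g$start, g$end, gid, NA),
             line("mRNA", g$start, g$end, tid, gid))
    exon <- g$exon_blocks[[1]]
    exon <- exon[order(exon[, 1L]), , drop = FALSE]
    for (j in seq_len(nrow(exon))) {
      out <- c(out,
               line("exon", exon[j, 1L], exon[j, 2L],
                    sprintf("%s.exon%d", tid, j), tid))
    }
    cds <- g$cds_blocks[[1]]
    if (nrow(cds)) {
      cds <- cds[order(cds[, 1L]), , drop = FALSE]
      for (j in seq_len(nrow(cds))) {
        out <- c(out,
                 line("CDS", cds[j, 1L], cds[j, 2L],
                      sprintf("%s.cds%d", tid, j), tid))
      }
    }
    writeLines(out, con)
  }
  invisible(path)
}
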