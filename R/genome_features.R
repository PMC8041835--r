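## Annotation readers and motif-to-feature assignment.
##
## Gene models are read from GFF3 (1-based inclusive) and converted to
## 0-based half-open coordinates. One model per gene: the first mRNA record
## in file order (high-confidence plant annotations are effectively one
## transcript per gene). CDS and exon blocks are stored in transcription
## order (5'->3' of the gene).

#' Read gene models from a GFF3 file
#'
#' @param gff3_path Path to a GFF3 annotation with gene / mRNA / exon / CDS
#'   features carrying `ID` / `Parent` links.
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open gene body), `confidence`, `has_cds`,
#'   `n_exons`, and list-columns `cds_blocks` / `exon_blocks` (two-column
#'   matrices of 0-based half-open blocks in transcription order).
#' @export
read_genes <- function(gff3_path) {
  g <- rtracklayer::readGFF(gff3_path)
  g <- as.data.frame(g)
  type <- as.character(g$type)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_,
           character(1))
  }
  parent <- if ("Parent" %in% names(g)) first_parent(g$Parent) else
    rep(NA_character_, nrow(g))
  id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))

  genes <- g[type == "gene", , drop = FALSE]
  gene_ids <- as.character(genes$ID)
  conf <- rep(NA_character_, nrow(genes))
  for (key in c("primary_confidence_class", "confidence")) {
    if (key %in% names(genes)) {
      v <- as.character(genes[[key]])
      conf[is.na(conf) & !is.na(v)] <- v[is.na(conf) & !is.na(v)]
    }
  }

  mrna <- g[type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_parent <- parent[type %in% c("mRNA", "transcript")]
  orphan <- !is.na(mrna_parent) & !(mrna_parent %in% gene_ids)
  if (any(orphan)) {
    warning(sprintf("skipping %d transcript(s) without a parent gene",
                    sum(orphan)))
    mrna <- mrna[!orphan, , drop = FALSE]
    mrna_parent <- mrna_parent[!orphan]
  }
  # first transcript per gene, in file order
  keep_tx <- !duplicated(mrna_parent)
  tx_of_gene <- stats::setNames(as.character(mrna$ID)[keep_tx],
                                mrna_parent[keep_tx])

  child <- g[type %in% c("CDS", "exon"), , drop = FALSE]
  child_parent <- parent[type %in% c("CDS", "exon")]
  known_tx <- as.character(mrna$ID)
  orphan_child <- !is.na(child_parent) & !(child_parent %in% known_tx) &
    !(child_parent %in% gene_ids)
  if (any(orphan_child)) {
    warning(sprintf("skipping %d CDS/exon feature(s) without a known parent",
                    sum(orphan_child)))
    child <- child[!orphan_child, , drop = FALSE]
    child_parent <- child_parent[!orphan_child]
  }

  blocks_of <- function(tx_id, gid, what, strand) {
    sel <- child_parent %in% c(tx_id, gid) & as.character(child$type) == what
    if (!any(sel)) return(matrix(integer(), ncol = 2L))
    b <- cbind(start = as.integer(child$start[sel]) - 1L,
               end = as.integer(child$end[sel]))
    b <- b[order(b[, 1L]), , drop = FALSE]
    if (strand == "-") b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
    b
  }

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- gene_ids[i]
    strand <- as.character(genes$strand[i])
    tx <- if (gid %in% names(tx_of_gene)) tx_of_gene[[gid]] else NA_character_
    cds <- blocks_of(tx, gid, "CDS", strand)
    exon <- blocks_of(tx, gid, "exon", strand)
    tibble::tibble(
      gene_id = gid,
      chrom = as.character(genes$seqid[i]),
      strand = strand,
      start = as.integer(genes$start[i]) - 1L,
      end = as.integer(genes$end[i]),
      confidence = conf[i],
      has_cds = nrow(cds) > 0L,
      n_exons = nrow(exon),
      cds_blocks = list(cds),
      exon_blocks = list(exon)
    )
  })
  dplyr::bind_rows(rows)
}

#' Read a SNP table
#'
#' Expects a TSV with columns `marker_id`, `chrom`, `pos` (1-based, converted
#' to 0-based on read), `ref`, `alt` — the layout of a Barley 50k iSelect
#' style marker export.
#'
#' @param path TSV path.
#' @return Tibble with `marker_id`, `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
read_snps <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[1:5] <- c("marker_id", "chrom", "pos", "ref", "alt")
  stopifnot(all(d$ref %in% c("A", "C", "G", "T")),
            all(d$alt %in% c("A", "C", "G", "T")))
  tibble::tibble(marker_id = as.character(d$marker_id),
                 chrom = as.character(d$chrom),
                 pos = as.integer(d$pos) - 1L,
                 ref = d$ref, alt = d$alt)
}

#' Read a gene-to-GO annotation map
#'
#' Expects TSV lines `gene_id<TAB>GO:NNNNNNN[,GO:...]`.
#'
#' @param path TSV path.
#' @return Long tibble with columns `gene_id`, `term`.
#' @export
read_go_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[1:2] <- c("gene_id", "terms")
  terms <- strsplit(d$terms, ",", fixed = TRUE)
  tibble::tibble(gene_id = rep(d$gene_id, lengths(terms)),
                 term = unlist(terms))
}

#' Read transposable-element intervals from BED or GFF3
#'
#' @param path File path; `.bed` is read as 0-based half-open with an
#'   optional 4th column giving the TE family, otherwise GFF3 is assumed
#'   (family taken from the `type` column).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `family`.
#' @export
read_tes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    tibble::tibble(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
                   end = as.integer(d[[3]]),
                   family = if (ncol(d) >= 4) as.character(d[[4]]) else NA)
  } else {
    g <- as.data.frame(rtracklayer::readGFF(path))
    tibble::tibble(chrom = as.character(g$seqid),
                   start = as.integer(g$start) - 1L,
                   end = as.integer(g$end),
                   family = as.character(g$type))
  }
}

## Overlap two 0-based half-open interval tables per chromosome.
## Returns a data.frame of (qi, si) index pairs; >=1 bp overlap.
overlap_pairs <- function(q, s) {
  if (nrow(q) == 0L || nrow(s) == 0L) {
    return(data.frame(qi = integer(), si = integer()))
  }
  out <- lapply(intersect(unique(q$chrom), unique(s$chrom)), function(ch) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start[qi] + 1L, q$end[qi]),
      IRanges::IRanges(s$start[si] + 1L, s$end[si]))
    data.frame(qi = qi[S4Vectors::queryHits(hits)],
               si = si[S4Vectors::subjectHits(hits)])
  })
  do.call(rbind, c(out, list(data.frame(qi = integer(), si = integer()))))
}

## Category intervals for one gene, 0-based half-open genomic coordinates.
## Anchors: upstream_1k/downstream_1k at the start codon / gene 3' end;
## flank5_500/flank3_500 at the gene body ends; cds/intron split into
## first (transcription order) vs rest.
gene_category_intervals <- function(gene, flank_small = 500L,
                                    flank_large = 1000L) {
  plus <- gene$strand == "+"
  cds <- gene$cds_blocks[[1]]
  exon <- gene$exon_blocks[[1]]
  anchor5 <- if (nrow(cds) > 0L) {
    if (plus) cds[1L, 1L] else cds[1L, 2L]  # start codon position / bound
  } else {
    if (plus) gene$start else gene$end
  }
  rows <- list()
  add <- function(cat, s, e) {
    if (e > s) rows[[length(rows) + 1L]] <<-
        data.frame(category = cat, start = s, end = e)
  }
  if (plus) {
    add("upstream_1k", anchor5 - flank_large, anchor5)
    add("downstream_1k", gene$end, gene$end + flank_large)
    add("flank5_500", gene$start - flank_small, gene$start)
    add("flank3_500", gene$end, gene$end + flank_small)
  } else {
    add("upstream_1k", anchor5, anchor5 + flank_large)
    add("downstream_1k", gene$start - flank_large, gene$start)
    add("flank5_500", gene$end, gene$end + flank_small)
    add("flank3_500", gene$start - flank_small, gene$start)
  }
  add("gene_body", gene$start, gene$end)
  if (nrow(cds) > 0L) {
    add("cds_first", cds[1L, 1L], cds[1L, 2L])
    for (i in seq_len(nrow(cds))[-1L]) add("cds_rest", cds[i, 1L], cds[i, 2L])
  }
  if (nrow(exon) >= 2L) {
    # introns in transcription order: gaps between consecutive exon blocks
    for (i in seq_len(nrow(exon) - 1L)) {
      a <- exon[i, ]; b <- exon[i + 1L, ]
      s <- if (plus) a[2L] else b[2L]
      e <- if (plus) b[1L] else a[1L]
      add(if (i == 1L) "intron_first" else "intron_rest", s, e)
    }
  }
  out <- do.call(rbind, rows)
  out$chrom <- gene$chrom
  out$gene_id <- gene$gene_id
  out
}

#' Assign motifs to gene structural categories
#'
#' A motif is assigned every category whose interval it overlaps by at least
#' 1 bp; a motif may hit several genes. Within one (motif, gene) pair,
#' `cds_first` and `cds_rest` are mutually exclusive (`cds_first` wins), and
#' likewise `intron_first` / `intron_rest`.
#'
#' @param motifs Motif tibble (0-based half-open).
#' @param genes Gene tibble from [read_genes()].
#' @param flank_small,flank_large Flank sizes in bp for the 500-bp UTR-proxy
#'   flanks and the 1-kb upstream/downstream windows.
#' @return Long tibble with `motif_id`, `gene_id`, `category`, plus the
#'   gene-relative strand `relation` (`"sense"` / `"antisense"`).
#' @export
assign_motifs <- function(motifs, genes, flank_small = 500L,
                          flank_large = 1000L) {
  if (nrow(motifs) == 0L || nrow(genes) == 0L) {
    return(tibble::tibble(motif_id = character(), gene_id = character(),
                          category = character(), relation = character()))
  }
  cats <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    gene_category_intervals(genes[i, ], flank_small, flank_large)
  }))
  hits <- overlap_pairs(motifs, cats)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(motif_id = character(), gene_id = character(),
                          category = character(), relation = character()))
  }
  out <- tibble::tibble(
    motif_id = motifs$motif_id[hits$qi],
    gene_id = cats$gene_id[hits$si],
    category = cats$category[hits$si],
    relation = ifelse(
      motifs$strand[hits$qi] ==
        genes$strand[match(cats$gene_id[hits$si], genes$gene_id)],
      "sense", "antisense")
  )
  out <- dplyr::distinct(out)
  # cds_first / intron_first exclusivity per (motif, gene)
  drop_rest <- function(d, first, rest) {
    key <- paste(d$motif_id, d$gene_id)
    has_first <- key %in% key[d$category == first]
    d[!(d$category == rest & has_first), , drop = FALSE]
  }
  out <- drop_rest(out, "cds_first", "cds_rest")
  out <- drop_rest(out, "intron_first", "intron_rest")
  out
}

#' Flag genes containing a G4 motif within the gene body plus flanks
#'
#' @inheritParams assign_motifs
#' @param flank Flank size in bp around the gene body (default 500).
#' @return Tibble `gene_id`, `has_g4`.
#' @export
genes_with_g4 <- function(motifs, genes, flank = 500L) {
  regions <- tibble::tibble(chrom = genes$chrom,
                            start = pmax(genes$start - as.integer(flank), 0L),
                            end = genes$end + as.integer(flank))
  hits <- overlap_pairs(motifs, regions)
  tibble::tibble(gene_id = genes$gene_id,
                 has_g4 = seq_len(nrow(genes)) %in% hits$si)
}

#' Count motifs overlapping transposable elements
#'
#' A motif inside nested or overlapping TE records counts once toward
#' `n_in_te`; per-family tallies count each overlapping family once per
#' motif.
#'
#' @param motifs Motif tibble.
#' @param te_intervals TE tibble from [read_tes()] (or compatible).
#' @return List with `n_in_te`, `fraction` (`n_in_te / nrow(motifs)`), and
#'   `per_family` (named integer vector).
#' @export
overlap_tes <- function(motifs, te_intervals) {
  if (nrow(motifs) == 0L || nrow(te_intervals) == 0L) {
    return(list(n_in_te = 0L, fraction = 0, per_family = integer()))
  }
  hits <- overlap_pairs(motifs, te_intervals)
  n_in <- length(unique(hits$qi))
  fam <- te_intervals$family[hits$si]
  per_family <- if (nrow(hits)) {
    pairs <- unique(data.frame(qi = hits$qi, fam = fam))
    tab <- table(pairs$fam)
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  list(n_in_te = n_in, fraction = n_in / nrow(motifs), per_family = per_family)
}

#' Locate SNPs falling inside motifs
#'
#' Half-open semantics: a SNP at the motif start is included (offset 0), a
#' SNP at the motif end coordinate is excluded. One row per (SNP, motif)
#' pair.
#'
#' @param motifs Motif tibble.
#' @param snps SNP tibble from [read_snps()].
#' @return Tibble of SNP rows with `motif_id` and `offset_in_motif` (0-based
#'   offset from the motif's forward-strand start).
#' @export
snps_in_motifs <- function(motifs, snps) {
  pts <- tibble::tibble(chrom = snps$chrom, start = snps$pos,
                        end = snps$pos + 1L)
  hits <- overlap_pairs(pts, motifs)
  out <- snps[hits$qi, , drop = FALSE]
  out$motif_id <- motifs$motif_id[hits$si]
  out$offset_in_motif <- snps$pos[hits$qi] - motifs$start[hits$si]
  out
}

#' Classify whether a SNP disrupts a perfect G4 motif
#'
#' The motif sequence is parsed greedily into stems and loops. A SNP in a
#' loop or in the +/- 10 bp flank is `loop_or_flank`. A SNP in a stem is
#' applied to the local sequence (motif +/- 10 bp) and the span is rescanned:
#' if a perfect motif on the same strand still overlaps the original span
#' (alternative stems or G-runs sliding off the variation site), the SNP is
#' `stem_tolerated`, otherwise `stem_disruptive`.
#'
#' @param motif One motif row (class `perfect` or `multimeric`).
#' @param snp One SNP row (0-based `pos`, forward-strand `ref` / `alt`).
#' @param genome Named character genome containing the motif's chromosome.
#' @return One of `"stem_disruptive"`, `"stem_tolerated"`, `"loop_or_flank"`.
#' @export
classify_snp_disruption <- function(motif, snp, genome) {
  genome <- as_genome(genome)
  stopifnot(motif$chrom %in% names(genome),
            motif$motif_class %in% c("perfect", "multimeric"))
  chseq <- genome[[motif$chrom]]
  flank <- 10L
  if (snp$pos < motif$start - flank || snp$pos >= motif$end + flank) {
    stop("SNP lies outside the motif and its +/-10 bp flank", call. = FALSE)
  }
  if (snp$pos < motif$start || snp$pos >= motif$end) {
    return("loop_or_flank")
  }
  # offset of the SNP inside motif_seq as read on the motif strand (1-based)
  i <- if (motif$strand == "+") snp$pos - motif$start + 1L
       else motif$end - snp$pos
  parse <- g4_parse(motif$motif_seq)
  if (is.null(parse)) {
    stop("motif_seq does not parse as a perfect G4 motif", call. = FALSE)
  }
  in_stem <- any(vapply(parse, function(b) i >= b[1L] && i < b[1L] + b[2L],
                        logical(1)))
  if (!in_stem) return("loop_or_flank")
  # mutate the forward-strand local window and rescan the same strand
  lo <- max(motif$start - flank, 0L)
  hi <- min(motif$end + flank, nchar(chseq))
  local <- substring(chseq, lo + 1L, hi)
  at <- snp$pos - lo + 1L
  substr(local, at, at) <- snp$alt
  rescan <- scan_both_strands(local, id = "local", mode = "perfect")
  rescan <- rescan[rescan$strand == motif$strand, , drop = FALSE]
  orig <- c(motif$start - lo, motif$end - lo)  # local 0-based half-open
  survives <- any(rescan$start < orig[2L] & rescan$end > orig[1L])
  if (survives) "stem_tolerated" else "stem_disruptive"
}
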