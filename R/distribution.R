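## Densities, anchored positional profiles, smoothing and genome bins.
##
## Density is the total number of motifs overlapping a region set, per Mb of
## unioned region length. Frequency is positional: within windows anchored at
## the start codon (= first CDS start) or the first intron start, every base
## a motif covers increments the tally at its gene-oriented offset, split by
## gene-relative strand. Dividing by the number of anchored regions gives the
## per-position fraction; the per-Mb variant multiplies that fraction by 1e6.

#' Per-feature G4 motif density
#'
#' @param motifs Motif tibble.
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param feature_class Label for the output row.
#' @return One-row tibble `(feature_class, n_motifs, span_bp, density_per_Mb)`
#'   with `density_per_Mb = n_motifs / span_bp * 1e6` and `span_bp` the
#'   unioned region length.
#' @export
g4_density <- function(motifs, regions, feature_class = "region") {
  stopifnot(nrow(regions) > 0L)
  span <- sum(vapply(split(regions, regions$chrom), function(r) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))))
  }, numeric(1)))
  if (span <= 0) stop("regions have zero total span", call. = FALSE)
  hits <- overlap_pairs(motifs, regions)
  n <- length(unique(hits$qi))
  tibble::tibble(feature_class = feature_class, n_motifs = n,
                 span_bp = span, density_per_Mb = n / span * 1e6)
}

## Anchor (0-based genomic position of the anchor base) per gene, or NA if
## the gene lacks the anchor. start_codon and cds_start are synonyms: the
## annotated first CDS start, oriented by gene strand.
gene_anchor <- function(gene, anchor_kind) {
  plus <- gene$strand == "+"
  if (anchor_kind %in% c("start_codon", "cds_start")) {
    cds <- gene$cds_blocks[[1]]
    if (nrow(cds) == 0L) return(NA_integer_)
    if (plus) cds[1L, 1L] else cds[1L, 2L] - 1L
  } else {  # intron1_start
    exon <- gene$exon_blocks[[1]]
    if (nrow(exon) < 2L) return(NA_integer_)
    if (plus) exon[1L, 2L] else exon[1L, 1L] - 1L
  }
}

#' Positional motif frequency around a gene anchor
#'
#' For each eligible gene a window of `2 * half_width` positions is anchored
#' at the chosen landmark and oriented 5'->3' along the gene (negative
#' offsets are gene-upstream of the anchor). Each genomic base covered by a
#' motif increments the tally at its offset, on the gene-relative strand of
#' the motif (`sense` = motif strand equals gene strand). With
#' `mode = "start"` only the motif's 5'-most covered offset is tallied.
#'
#' @param motifs Motif tibble.
#' @param genes Gene tibble from [read_genes()].
#' @param anchor_kind `"start_codon"`, `"cds_start"` (synonym) or
#'   `"intron1_start"` (requires >= 2 exons).
#' @param half_width Window half-width in bp (default 5000).
#' @param normalize `"none"` (raw counts), `"fraction"` (divide by the number
#'   of anchored genes) or `"per_Mb"` (fraction times 1e6).
#' @param mode `"coverage"` (default, per covered base) or `"start"`.
#' @return A `g4_profile` object: list with `offsets`
#'   (`-half_width .. half_width - 1`), `counts_sense`, `counts_antisense`,
#'   `counts_both` (raw tallies), `n_regions`, `anchor_kind`, `normalize`.
#'   Use [profile_values()] for the normalised table.
#' @export
positional_frequency <- function(motifs, genes,
                                 anchor_kind = c("start_codon", "cds_start",
                                                 "intron1_start"),
                                 half_width = 5000L,
                                 normalize = c("none", "fraction", "per_Mb"),
                                 mode = c("coverage", "start")) {
  anchor_kind <- match.arg(anchor_kind)
  normalize <- match.arg(normalize)
  mode <- match.arg(mode)
  half_width <- as.integer(half_width)
  anchors <- vapply(seq_len(nrow(genes)),
                    function(i) gene_anchor(genes[i, ], anchor_kind),
                    numeric(1))
  eligible <- which(!is.na(anchors))
  if (length(eligible) == 0L) {
    stop("no genes carry the requested anchor", call. = FALSE)
  }
  wlen <- 2L * half_width
  sense <- integer(wlen)
  anti <- integer(wlen)
  # windows in genomic coordinates (may be truncated at chromosome edges);
  # gene-oriented offsets [-hw, hw) map to genomic [a-hw, a+hw) on "+" genes
  # and [a-hw+1, a+hw+1) on "-" genes
  plus_g <- genes$strand[eligible] == "+"
  a_g <- as.integer(anchors[eligible])
  win <- tibble::tibble(
    chrom = genes$chrom[eligible],
    start = pmax(0L, ifelse(plus_g, a_g - half_width, a_g - half_width + 1L)),
    end = ifelse(plus_g, a_g + half_width, a_g + half_width + 1L)
  )
  hits <- overlap_pairs(motifs, win)
  off_sense <- integer(0); off_anti <- integer(0)
  if (nrow(hits)) {
    for (h in seq_len(nrow(hits))) {
      mi <- hits$qi[h]; wi <- hits$si[h]
      gi <- eligible[wi]
      a <- anchors[gi]
      plus <- genes$strand[gi] == "+"
      s <- max(motifs$start[mi], if (plus) a - half_width else a - half_width + 1L)
      e <- min(motifs$end[mi], if (plus) a + half_width else a + half_width + 1L)
      if (e <= s) next
      offs <- if (plus) (s:(e - 1L)) - a else a - ((e - 1L):s)
      offs <- offs[offs >= -half_width & offs < half_width]
      if (mode == "start") offs <- min(offs)
      if (motifs$strand[mi] == genes$strand[gi]) {
        off_sense <- c(off_sense, offs)
      } else {
        off_anti <- c(off_anti, offs)
      }
    }
  }
  idx <- function(o) o + half_width + 1L
  if (length(off_sense)) sense <- tabulate(idx(off_sense), nbins = wlen)
  if (length(off_anti)) anti <- tabulate(idx(off_anti), nbins = wlen)
  structure(list(offsets = seq.int(-half_width, half_width - 1L),
                 counts_sense = sense, counts_antisense = anti,
                 counts_both = sense + anti,
                 n_regions = length(eligible), anchor_kind = anchor_kind,
                 normalize = normalize, mode = mode),
            class = "g4_profile")
}

#' Normalised values of a positional profile
#'
#' @param profile A `g4_profile`.
#' @param normalize Overrides the profile's `normalize` field if given.
#' @return Tibble `(offset, sense, antisense, both)` on the requested scale.
#' @export
profile_values <- function(profile, normalize = NULL) {
  normalize <- if (is.null(normalize)) profile$normalize else normalize
  f <- switch(normalize,
              none = 1,
              fraction = 1 / profile$n_regions,
              per_Mb = 1e6 / profile$n_regions,
              stop("unknown normalize mode", call. = FALSE))
  tibble::tibble(offset = profile$offsets,
                 sense = profile$counts_sense * f,
                 antisense = profile$counts_antisense * f,
                 both = profile$counts_both * f)
}

#' @export
print.g4_profile <- function(x, ...) {
  cat(sprintf("g4_profile: anchor=%s, n_regions=%d, %d offsets, %d motif-base tallies\n",
              x$anchor_kind, x$n_regions, length(x$offsets), sum(x$counts_both)))
  invisible(x)
}

#' Centered moving-average smoothing of a profile
#'
#' Shrinking windows at the array edges (no padding): position `i` averages
#' over the available span `[i - w/2, i + w/2]` truncated to the profile.
#' `window = 1` is the identity.
#'
#' @param x A `g4_profile` or a numeric vector.
#' @param window Odd window size in bp (the study compares 999, 199, 99, 1).
#' @return Same type as `x`, smoothed.
#' @export
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (inherits(x, "g4_profile")) {
    stopifnot(window <= length(x$offsets))
    x$counts_sense <- moving_average(as.numeric(x$counts_sense), window)
    x$counts_antisense <- moving_average(as.numeric(x$counts_antisense), window)
    x$counts_both <- x$counts_sense + x$counts_antisense
    x$window <- window
    return(x)
  }
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Count local maxima (plateau-aware) of a numeric profile
#'
#' A maximal run of equal values (up to `tol`) counts as one local maximum
#' when it is strictly greater than both neighbouring values (array
#' boundaries count as -Inf). The default tolerance absorbs the
#' floating-point jitter a running-sum moving average introduces on flat
#' stretches.
#'
#' @param x Numeric vector.
#' @param tol Equality tolerance; values are quantised to multiples of it.
#' @return Integer count of local maxima.
#' @export
count_local_maxima <- function(x, tol = NULL) {
  x <- as.numeric(x)
  if (is.null(tol)) tol <- 1e-8 * max(abs(x), 1e-300)
  r <- rle(round(x / tol))
  v <- c(-Inf, r$values, -Inf)
  n <- length(r$values)
  sum(vapply(seq_len(n), function(i) {
    v[i + 1L] > v[i] && v[i + 1L] > v[i + 2L]
  }, logical(1)))
}

#' Genes whose anchored peak regions contain an antisense motif
#'
#' Peak definitions, gene-oriented around the start codon: `peak1` is
#' `[-250, 0)` (the 5' UTR side), `peak2` is `[0, +250)` (first CDS side),
#' and `peak3` is the first 100 bp of intron 1 (multi-exon genes only). All
#' peaks are scored on the gene-antisense strand; the sets may intersect.
#'
#' @inheritParams positional_frequency
#' @return Named list of gene-id character vectors `peak1`, `peak2`, `peak3`.
#' @export
peak_gene_sets <- function(motifs, genes) {
  peak_window <- function(gene, from, to, anchor_kind) {
    a <- gene_anchor(gene, anchor_kind)
    if (is.na(a)) return(NULL)
    if (gene$strand == "+") c(a + from, a + to) else c(a - to + 1L, a - from + 1L)
  }
  anti <- function(gene) if (gene$strand == "+") "-" else "+"
  collect <- function(from, to, anchor_kind, multi_only = FALSE) {
    ids <- character(0)
    for (i in seq_len(nrow(genes))) {
      gene <- genes[i, ]
      if (multi_only && gene$n_exons < 2L) next
      w <- peak_window(gene, from, to, anchor_kind)
      if (is.null(w)) next
      sel <- motifs$chrom == gene$chrom & motifs$strand == anti(gene) &
        motifs$start < w[2L] & motifs$end > w[1L]
      if (any(sel)) ids <- c(ids, gene$gene_id)
    }
    ids
  }
  list(peak1 = collect(-250L, 0L, "start_codon"),
       peak2 = collect(0L, 250L, "start_codon"),
       peak3 = collect(0L, 100L, "intron1_start", multi_only = TRUE))
}

#' Bin features along chromosomes (Circos histogram input)
#'
#' Each chromosome is split into `n_bins` equal-width bins (the last bin
#' absorbs the remainder); features are binned by their start coordinate.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param features Tibble with `chrom`, `start`.
#' @param n_bins Number of bins per chromosome (default 1000).
#' @return Tibble `(chrom, bin_start, bin_end, count)` covering every bin.
#' @export
bin_genome <- function(chrom_lengths, features, n_bins = 1000L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    w <- max(L %/% n_bins, 1L)
    bs <- seq.int(0L, by = w, length.out = n_bins)
    be <- c(bs[-1L], L)
    st <- features$start[features$chrom == ch]
    bin <- pmin(st %/% w, n_bins - 1L)
    tibble::tibble(chrom = ch, bin_start = bs, bin_end = be,
                   count = tabulate(bin + 1L, nbins = n_bins))
  })
  dplyr::bind_rows(out)
}
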