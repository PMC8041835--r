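## Shuffle-based genic enrichment, random backgrounds and GO statistics.

#' Shuffle intervals uniformly across a genome
#'
#' Each interval keeps its length and is placed independently at random: the
#' chromosome is chosen with probability proportional to its length (among
#' chromosomes the interval fits on) and the start uniformly over the valid
#' range. Shuffled intervals may overlap each other; no exclusion zones are
#' applied.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed for reproducibility.
#' @param n_reps Number of independent shuffles.
#' @return A list of `n_reps` shuffled region tibbles.
#' @export
shuffle_intervals <- function(regions, chrom_lengths, seed = NULL,
                              n_reps = 1L) {
  if (!is.null(seed)) set.seed(seed)
  lens <- regions$end - regions$start
  chl <- as.numeric(chrom_lengths)
  names(chl) <- names(chrom_lengths)
  if (any(lens > max(chl))) {
    stop("a region is longer than every chromosome", call. = FALSE)
  }
  lapply(seq_len(n_reps), function(rep) {
    chrom <- character(length(lens))
    start <- integer(length(lens))
    for (i in seq_along(lens)) {
      fits <- which(chl >= lens[i])
      ch <- if (length(fits) == 1L) fits else
        sample(fits, 1L, prob = chl[fits])
      chrom[i] <- names(chl)[ch]
      # start uniform over 0 .. L - len (forced to 0 when L == len)
      start[i] <- floor(stats::runif(1, min = 0, max = chl[ch] - lens[i] + 1))
      if (start[i] > chl[ch] - lens[i]) start[i] <- chl[ch] - lens[i]
    }
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(start + lens))
  })
}

#' Fold enrichment of motifs in regions versus shuffled placements
#'
#' Counts motifs overlapping the real regions, then the mean motif overlap of
#' `n_reps` random shuffles of the same intervals; the ratio of the two is
#' the fold enrichment (the study's genic-region enrichment statistic).
#'
#' @inheritParams shuffle_intervals
#' @param motifs Motif tibble.
#' @return List with `seed`, `n_intervals`, `observed_overlap`,
#'   `shuffled_overlap` (mean), `shuffled_reps` (per-rep counts), `fold`.
#' @export
fold_enrichment <- function(motifs, regions, chrom_lengths, seed = NULL,
                            n_reps = 1L) {
  observed <- length(unique(overlap_pairs(motifs, regions)$qi))
  shufs <- shuffle_intervals(regions, chrom_lengths, seed = seed,
                             n_reps = n_reps)
  reps <- vapply(shufs, function(s) {
    length(unique(overlap_pairs(motifs, s)$qi))
  }, numeric(1))
  shuffled <- mean(reps)
  if (shuffled == 0) {
    stop("shuffled overlap is zero; increase n_reps", call. = FALSE)
  }
  list(seed = seed, n_intervals = nrow(regions), observed_overlap = observed,
       shuffled_overlap = shuffled, shuffled_reps = reps,
       fold = observed / shuffled)
}

#' Median G4 density of iid random sequence backgrounds
#'
#' Generates three independent iid uniform `{A,C,G,T}` datasets of
#' `total_bp` each, scans each with `scan_fn`, and returns the median of the
#' three densities (all three are kept for audit).
#'
#' @param total_bp Size of each random dataset in bp (>= 1e5).
#' @param seed Optional integer seed.
#' @param scan_fn Function mapping a named genome to a motif tibble; defaults
#'   to the both-strand perfect scan.
#' @return List with `density_per_Mb` (median), `densities` (length 3), and
#'   `n_motifs` per dataset.
#' @export
random_background_density <- function(total_bp, seed = NULL,
                                      scan_fn = function(g) scan_genome(g, "perfect")) {
  stopifnot(total_bp >= 1e5)
  if (!is.null(seed)) set.seed(seed)
  counts <- numeric(3)
  for (k in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T"), total_bp, replace = TRUE),
                 collapse = "")
    counts[k] <- nrow(scan_fn(stats::setNames(list(seq), sprintf("rand%d", k))))
  }
  dens <- counts / total_bp * 1e6
  list(density_per_Mb = stats::median(dens), densities = dens,
       n_motifs = counts)
}

go_table <- function(term_genes, g4_genes, all_genes) {
  a <- sum(term_genes %in% g4_genes)
  n_g4 <- length(g4_genes)
  n_term <- length(term_genes)
  b <- n_g4 - a
  c_ <- n_term - a
  d <- length(all_genes) - n_g4 - c_
  c(a = a, b = b, c = c_, d = d)
}

#' Pearson chi-square association of GO terms with G4-containing genes
#'
#' For each term, a 2x2 table (G4-gene x term membership) over the gene
#' universe is tested with Pearson's chi-square (no continuity correction by
#' default, as in a plain Pearson test); Benjamini-Hochberg q-values are
#' added across terms, and terms with any expected cell below 5 are flagged.
#'
#' @param g4_genes Character vector of G4-containing gene ids (subset of
#'   `all_genes`).
#' @param all_genes Character vector: the gene universe.
#' @param go_map Long tibble `(gene_id, term)`.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Tibble with `term`, counts `a`, `b`, `c`, `d`, `statistic`,
#'   `p_value`, `q_value`, `low_expected`.
#' @export
go_chi_square <- function(g4_genes, all_genes, go_map, correct = FALSE) {
  stopifnot(length(all_genes) > 0L, all(g4_genes %in% all_genes))
  go_map <- go_map[go_map$gene_id %in% all_genes, , drop = FALSE]
  terms <- split(go_map$gene_id, go_map$term)
  rows <- lapply(names(terms), function(tm) {
    ct <- go_table(unique(terms[[tm]]), g4_genes, all_genes)
    m <- matrix(ct, nrow = 2L, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    res <- suppressWarnings(stats::chisq.test(m, correct = correct))
    tibble::tibble(term = tm, a = ct[["a"]], b = ct[["b"]], c = ct[["c"]],
                   d = ct[["d"]],
                   statistic = unname(res$statistic),
                   p_value = unname(res$p.value),
                   low_expected = any(expected < 5))
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("term", "a", "b", "c", "d", "statistic", "p_value", "q_value",
          "low_expected")]
}

#' Hypergeometric GO term over-representation test
#'
#' Per-term over-representation p-value via the hypergeometric upper tail
#' (probability of observing at least the seen number of annotated genes in
#' the subset), with Benjamini-Hochberg correction; `enriched` flags terms
#' with `q_value <= alpha`. Terms with no annotated genes in the universe are
#' skipped with a warning.
#'
#' @param subset Character vector of selected gene ids.
#' @param universe Character vector: the gene universe (`subset` within it).
#' @param go_map Long tibble `(gene_id, term)`.
#' @param alpha Significance level on the q-value (default 0.05).
#' @return Tibble with `term`, `k` (subset hits), `K` (term size), `n`
#'   (subset size), `N` (universe size), `p_value`, `q_value`, `enriched`.
#' @export
go_hypergeometric <- function(subset, universe, go_map, alpha = 0.05) {
  stopifnot(length(universe) > 0L, all(subset %in% universe))
  go_map <- go_map[go_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(go_map$gene_id, go_map$term)
  sizes <- vapply(terms, function(g) length(unique(g)), integer(1))
  if (any(sizes == 0L)) {
    warning("skipping empty GO terms")
    terms <- terms[sizes > 0L]
  }
  N <- length(universe)
  n <- length(subset)
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    K <- length(tg)
    k <- sum(tg %in% subset)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = tm, k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$q_value <= alpha
  out
}
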