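## Imperfect (bulged-stem) G4 motif enumeration.
##
## A stem is either a contiguous block of stem_min..stem_max guanines (a
## sub-run of a longer G-run is allowed; stems use exactly stem_min..stem_max
## Gs, never more) or two G-blocks totalling stem_min..stem_max Gs separated
## by a single bulge of 1..max_bulge_len non-G bases. Candidates are chains of
## >= min_stems stems joined by loops of 1..max_loop arbitrary bases. Perfect
## (zero-bulge) motifs are therefore included. Candidates are reported as
## maximal-coverage spans, greedily per starting stem, and are meant to be
## merged; post-merge intervals are what downstream analyses consume.

#' Parameters for the imperfect G4 scan
#'
#' Defaults mirror a QPARSE-style parameterisation: G-stems of 3-4 guanines,
#' at most one bulge of up to 2 non-G bases per stem, loops up to 7 bases
#' (or 12 for the long-loop class), at least four stems.
#'
#' @param stem_min,stem_max Guanines per stem (defaults 3 and 4).
#' @param max_loop Maximum loop length in bp (7 for class `imperfect`, 12 for
#'   `imperfect_long`).
#' @param max_bulges_per_stem Bulges allowed inside one stem (default 1).
#' @param max_bulge_len Maximum bulge length in bp (default 2).
#' @param min_stems Minimum stems per motif (default 4).
#' @return A validated `imperfect_params` list.
#' @export
imperfect_params <- function(stem_min = 3L, stem_max = 4L, max_loop = 7L,
                             max_bulges_per_stem = 1L, max_bulge_len = 2L,
                             min_stems = 4L) {
  p <- list(stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
            max_loop = as.integer(max_loop),
            max_bulges_per_stem = as.integer(max_bulges_per_stem),
            max_bulge_len = as.integer(max_bulge_len),
            min_stems = as.integer(min_stems))
  stopifnot(p$stem_min >= 1L, p$stem_min <= p$stem_max, p$max_loop >= 1L,
            p$max_bulge_len >= 1L, p$min_stems >= 2L,
            p$max_bulges_per_stem == 1L)
  class(p) <- "imperfect_params"
  p
}

imperfect_class <- function(params) {
  if (params$max_loop > 7L) "imperfect_long" else "imperfect"
}

## Enumerate all stem intervals (1-based inclusive start/end) on one strand.
## base = "G" for forward, "C" for the antisense search on the forward
## sequence. Returns a two-column integer matrix (start, end), sorted.
enumerate_stems <- function(seq, base, params) {
  m <- gregexpr(paste0(base, "+"), seq)[[1]]
  if (m[1] == -1L) return(matrix(integer(), ncol = 2L))
  rs <- as.integer(m)                      # run starts
  rl <- attr(m, "match.length")            # run lengths
  re <- rs + rl - 1L                       # run ends
  starts <- integer(0)
  ends <- integer(0)
  # contiguous stems: every sub-run of stem_min..stem_max bases
  for (L in params$stem_min:params$stem_max) {
    ok <- rl >= L
    if (any(ok)) {
      n_sub <- rl[ok] - L + 1L
      st <- rep.int(rs[ok], n_sub) +
        (sequence(n_sub) - 1L)
      starts <- c(starts, st)
      ends <- c(ends, st + L - 1L)
    }
  }
  # bulged stems: suffix of run i + prefix of run i+1 with a 1..max_bulge_len
  # non-G (non-base) gap between; total Gs stem_min..stem_max, one bulge
  if (length(rs) >= 2L) {
    gap <- rs[-1L] - re[-length(re)] - 1L
    pair <- which(gap >= 1L & gap <= params$max_bulge_len)
    if (length(pair)) {
      combos <- expand.grid(l1 = 1L:(params$stem_max - 1L),
                            l2 = 1L:(params$stem_max - 1L))
      combos <- combos[combos$l1 + combos$l2 >= params$stem_min &
                       combos$l1 + combos$l2 <= params$stem_max, , drop = FALSE]
      for (k in seq_len(nrow(combos))) {
        l1 <- combos$l1[k]; l2 <- combos$l2[k]
        ok <- pair[rl[pair] >= l1 & rl[pair + 1L] >= l2]
        if (length(ok)) {
          starts <- c(starts, re[ok] - l1 + 1L)
          ends <- c(ends, rs[ok + 1L] + l2 - 1L)
        }
      }
    }
  }
  if (!length(starts)) return(matrix(integer(), ncol = 2L))
  stems <- unique(cbind(starts, ends))
  stems <- stems[order(stems[, 1L], stems[, 2L]), , drop = FALSE]
  stems
}

## Chain DP over stems: Dk[i] = maximal end coordinate reachable by a chain of
## >= k stems starting at stem i (successor = next stem with a loop of
## 1..max_loop bases between). Spans [start_i, D_min_stems[i]] are the
## maximal-coverage candidates; any longer chain's span is covered by the
## union of the spans of its 'min_stems'-stem windows.
chain_candidates <- function(stems, params) {
  m <- nrow(stems)
  if (m == 0L) return(stems)
  S <- stems[, 1L]; E <- stems[, 2L]
  k <- params$min_stems
  lo <- findInterval(E + 1L, S) + 1L              # first stem with S > E + 1
  hi <- findInterval(E + 1L + params$max_loop, S) # last with S <= E+1+max_loop
  D <- matrix(-Inf, nrow = m, ncol = k)           # D[, j] = chains of >= j
  C <- integer(m)                                 # longest chain length
  for (i in m:1L) {
    if (lo[i] <= hi[i]) {
      idx <- lo[i]:hi[i]
      best1 <- max(D[idx, 1L])
      D[i, 1L] <- max(E[i], best1)
      for (j in 2L:k) D[i, j] <- max(D[idx, j - 1L])
      C[i] <- 1L + max(C[idx])
    } else {
      D[i, 1L] <- E[i]
      C[i] <- 1L
    }
  }
  ok <- is.finite(D[, k])
  cbind(start = S[ok], end = D[ok, k], n_stems = C[ok])
}

#' Scan a sequence for imperfect (bulged) G4 motif candidates
#'
#' Enumerates bulged-stem candidates on both strands (C-pattern on the forward
#' sequence for the antisense strand). Each candidate is the maximal-coverage
#' span of chains of >= `min_stems` stems beginning at one stem; overlapping
#' candidates are expected to be collapsed with [merge_overlapping()], and
#' only the merged interval set is contract-stable.
#'
#' @inheritParams scan_perfect
#' @param params An [imperfect_params()] object.
#' @return Motif tibble of candidates (class `imperfect` or `imperfect_long`
#'   according to `params$max_loop`); `n_stems` is the longest chain length
#'   from the candidate's first stem.
#' @export
scan_imperfect <- function(x, id = "seq", params = imperfect_params()) {
  stopifnot(inherits(params, "imperfect_params"))
  rec <- as_record(x, id)
  cls <- imperfect_class(params)
  out <- lapply(c("G", "C"), function(base) {
    stems <- enumerate_stems(rec$seq, base, params)
    cand <- chain_candidates(stems, params)
    if (nrow(cand) == 0L) return(empty_motifs())
    seqs <- substring(rec$seq, cand[, "start"], cand[, "end"])
    motif_tbl(rec$id, cand[, "start"] - 1L, cand[, "end"],
              if (base == "C") "-" else "+", cls, cand[, "n_stems"],
              if (base == "C") revcomp(seqs) else seqs)
  })
  out <- dplyr::bind_rows(out)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Merge overlapping motif candidates into single motifs
#'
#' Per strand, overlapping or book-ended candidate intervals are unioned;
#' strands are never merged together. The number of collapsed candidates is
#' recorded in `n_candidates`.
#'
#' @param candidates Motif tibble on a single chromosome.
#' @param genome Optional named genome (to re-extract `motif_seq` for merged
#'   spans); if `NULL`, merged `motif_seq` is `NA` where spans changed.
#' @return Motif tibble with pairwise-disjoint intervals per strand, sorted,
#'   plus column `n_candidates`.
#' @export
merge_overlapping <- function(candidates, genome = NULL) {
  if (nrow(candidates) == 0L) {
    out <- empty_motifs()
    out$n_candidates <- integer()
    return(out)
  }
  if (length(unique(candidates$chrom)) > 1L) {
    stop("candidates must share one chromosome", call. = FALSE)
  }
  res <- lapply(split(candidates, candidates$strand), function(cc) {
    ir <- IRanges::IRanges(start = cc$start + 1L, end = cc$end)
    # min.gapwidth = 1 also merges book-ended half-open intervals
    red <- IRanges::reduce(ir, min.gapwidth = 1L)
    region <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    ncand <- tabulate(region, nbins = length(red))
    ns <- vapply(split(cc$n_stems, factor(region, levels = seq_along(red))),
                 max, numeric(1))
    st <- IRanges::start(red) - 1L
    en <- IRanges::end(red)
    seqs <- rep(NA_character_, length(red))
    if (!is.null(genome)) {
      chseq <- as_genome(genome)[[cc$chrom[1L]]]
      raw <- substring(chseq, st + 1L, en)
      seqs <- if (cc$strand[1L] == "-") revcomp(raw) else raw
    }
    out <- motif_tbl(cc$chrom[1L], st, en, cc$strand[1L],
                     cc$motif_class[1L], ns, seqs)
    out$n_candidates <- as.integer(ncand)
    out
  })
  out <- dplyr::bind_rows(res)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome for merged imperfect motifs
#'
#' Convenience wrapper running [scan_imperfect()] plus [merge_overlapping()]
#' per chromosome.
#'
#' @inheritParams scan_genome
#' @param params An [imperfect_params()] object.
#' @return Merged motif tibble across chromosomes.
#' @export
scan_genome_imperfect <- function(genome, params = imperfect_params()) {
  genome <- as_genome(genome)
  res <- lapply(names(genome), function(ch) {
    cand <- scan_imperfect(genome[[ch]], id = ch, params = params)
    merge_overlapping(cand, genome = genome[ch])
  })
  dplyr::bind_rows(res)
}
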