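## Perfect and multimeric G4 motif scanning.
##
## The perfect pattern is the quadparser one, (G3+ L1-7)3+ G3+: at least four
## runs of >=3 guanines separated by loops of 1-7 arbitrary bases. Matching is
## leftmost, greedy and non-overlapping per strand (the regex-engine
## convention): each G-run and the repeat count are extended maximally and the
## search resumes at the previous match end, so any continuous G4 stretch is
## counted once. Loops may contain any base including G and N; G-runs never
## contain N, so assembly gaps terminate stems rather than fabricating them.
## All coordinates are 0-based half-open (BED convention).

g4_pattern <- function(base = c("G", "C"), min_stems = 4L, max_loop = 7L) {
  base <- match.arg(base)
  sprintf("(?:%s{3,}[ACGTN]{1,%d}){%d,}%s{3,}", base, max_loop, min_stems - 1L, base)
}

empty_motifs <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif_class = character(),
                 n_stems = integer(), motif_seq = character(),
                 motif_id = character())
}

motif_tbl <- function(chrom, start, end, strand, motif_class, n_stems, motif_seq) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, motif_class = motif_class,
    n_stems = as.integer(n_stems), motif_seq = motif_seq,
    motif_id = sprintf("%s:%s:%d-%d:%s", motif_class, chrom, start, end, strand)
  )
}

scan_one_strand <- function(rec, base, min_stems, motif_class) {
  m <- gregexpr(g4_pattern(base, min_stems), rec$seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_motifs())
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  seqs <- substring(rec$seq, start1, start1 + len - 1L)
  if (base == "C") {
    strand <- "-"
    motif_seq <- revcomp(seqs)
  } else {
    strand <- "+"
    motif_seq <- seqs
  }
  n_stems <- vapply(motif_seq, count_stems, integer(1), USE.NAMES = FALSE)
  motif_tbl(rec$id, start1 - 1L, start1 - 1L + len, strand, motif_class,
            n_stems, motif_seq)
}

#' Scan one strand of a sequence for perfect G4 motifs
#'
#' Finds forward-strand motifs matching `(G{3,}[ACGTN]{1,7}){min_stems-1,}G{3,}`
#' with leftmost, greedy, non-overlapping semantics, sorted by start.
#'
#' @param x A [sequence_record()] or a nucleotide string.
#' @param id Sequence identifier when `x` is a bare string.
#' @param min_stems Minimum number of G-runs per motif (default 4).
#' @return Tibble of motifs with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `motif_class`, `n_stems`, `motif_seq`, `motif_id`.
#' @examples
#' scan_perfect("GGGAGGGTGGGAGGG")
#' @export
scan_perfect <- function(x, id = "seq", min_stems = 4L) {
  stopifnot(min_stems >= 2L)
  rec <- as_record(x, id)
  scan_one_strand(rec, "G", as.integer(min_stems), "perfect")
}

#' Scan one strand for multimeric G4 motifs (>= 8 G-stems)
#'
#' Same pattern as [scan_perfect()] but requiring at least eight G-runs per
#' match; every returned interval is also found (identically or as part of a
#' containing interval) by the perfect scan.
#'
#' @inheritParams scan_perfect
#' @return Motif tibble with `motif_class = "multimeric"`.
#' @export
scan_multimeric <- function(x, id = "seq") {
  rec <- as_record(x, id)
  scan_one_strand(rec, "G", 8L, "multimeric")
}

#' Scan both strands of a sequence
#'
#' The antisense search matches the complementary C-pattern
#' `(C{3,}[ACGTN]{1,7}){k,}C{3,}` on the forward sequence and reports
#' `strand = "-"` with `motif_seq` given as the reverse complement of the
#' forward-strand slice, so all coordinates stay on the forward strand.
#' Forward and reverse motifs may overlap each other.
#'
#' @inheritParams scan_perfect
#' @param mode `"perfect"` (>= `min_stems` runs) or `"multimeric"` (>= 8 runs).
#' @return Motif tibble sorted by `(start, strand)`.
#' @export
scan_both_strands <- function(x, id = "seq", mode = c("perfect", "multimeric"),
                              min_stems = 4L) {
  mode <- match.arg(mode)
  rec <- as_record(x, id)
  if (mode == "multimeric") min_stems <- 8L
  cls <- if (mode == "multimeric") "multimeric" else "perfect"
  fwd <- scan_one_strand(rec, "G", as.integer(min_stems), cls)
  rev <- scan_one_strand(rec, "C", as.integer(min_stems), cls)
  out <- dplyr::bind_rows(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a whole genome for G4 motifs on both strands
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @inheritParams scan_both_strands
#' @return Motif tibble across all chromosomes.
#' @export
scan_genome <- function(genome, mode = c("perfect", "multimeric"),
                        min_stems = 4L) {
  mode <- match.arg(mode)
  genome <- as_genome(genome)
  res <- lapply(names(genome), function(ch) {
    scan_both_strands(genome[[ch]], id = ch, mode = mode, min_stems = min_stems)
  })
  dplyr::bind_rows(res)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- read_genome_fasta(genome)
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(toupper(as.character(genome)), names(genome))
  } else if (is.list(genome)) {
    genome <- unlist(genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  as.list(genome)
}

#' Count G-stems in a perfect motif sequence
#'
#' Returns the number of repeat units in the leftmost-longest parse of the
#' perfect pattern over the full span, with the repeat count extended
#' maximally: of all decompositions of the sequence into (G-run, loop) units
#' plus a closing G-run, the one consuming the most units is used. This is
#' what makes an 8-run multimeric span report 8 stems even though shorter
#' decompositions (loops swallowing whole G-runs) also match.
#'
#' @param motif_seq Nucleotide string matching the perfect pattern end-to-end
#'   (as read 5'->3' on the motif strand, i.e. G-runs, not C-runs).
#' @return Integer stem count (>= 4 for perfect motifs).
#' @examples
#' count_stems("GGGAGGGTGGGAGGG")  # 4
#' @export
count_stems <- function(motif_seq) {
  p <- g4_parse(motif_seq)
  if (is.null(p)) {
    stop("motif_seq does not match the perfect G4 pattern over its full span",
         call. = FALSE)
  }
  length(p)
}

## Maximal-stem parse of the anchored perfect pattern. Dynamic program over
## suffixes: f[pos] = largest number of stems in a decomposition of
## motif_seq[pos..n] into (G{3,} stem, 1..max_loop loop) units plus a
## closing G{3,} run ending exactly at n. Returns a list of c(start, len)
## stem blocks (1-based), or NULL if the string does not match with
## >= min_stems stems. Reconstruction ties break toward longer stems, then
## shorter loops.
g4_parse <- function(motif_seq, max_loop = 7L, min_stems = 4L) {
  n <- nchar(motif_seq)
  if (n < 3L * min_stems + (min_stems - 1L)) return(NULL)
  ch <- strsplit(motif_seq, "", fixed = TRUE)[[1]]
  isG <- ch == "G"
  runlen <- integer(n)  # length of the G-run starting at each position
  acc <- 0L
  for (i in n:1) {
    acc <- if (isG[i]) acc + 1L else 0L
    runlen[i] <- acc
  }
  f <- rep(-Inf, n)
  for (pos in n:1L) {
    r <- runlen[pos]
    if (r < 3L) next
    best <- if (pos + r - 1L == n) 1 else -Inf  # closing run option
    g_max <- min(r, n - 3L - pos)  # leave room for a loop and closing run
    if (g_max >= 3L) {
      for (g in 3L:g_max) {
        l_max <- min(max_loop, n - 2L - pos - g)
        if (l_max < 1L) next
        sub <- f[(pos + g + 1L):(pos + g + l_max)]
        best <- max(best, 1 + max(sub))
      }
    }
    f[pos] <- best
  }
  if (!is.finite(f[1L]) || f[1L] < min_stems) return(NULL)
  # reconstruct one maximal decomposition
  stems <- list()
  pos <- 1L
  repeat {
    r <- runlen[pos]
    if (pos + r - 1L == n && f[pos] == 1) {
      stems[[length(stems) + 1L]] <- c(pos, r)
      break
    }
    found <- FALSE
    for (g in min(r, n - 3L - pos):3L) {
      if (found || g < 3L) break
      for (l in 1L:min(max_loop, n - 2L - pos - g)) {
        np <- pos + g + l
        if (is.finite(f[np]) && 1 + f[np] == f[pos]) {
          stems[[length(stems) + 1L]] <- c(pos, g)
          pos <- np
          found <- TRUE
          break
        }
      }
    }
    if (!found) return(NULL)  # should not happen for a matching string
  }
  stems
}
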