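# Independent oracles used to cross-check the scanners and statistics.
# These deliberately use different mechanisms from the implementation:
# exhaustive substring testing, plain recursive enumeration, closed forms.

random_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Leftmost-longest non-overlapping scan of one strand by testing every
# candidate substring against the anchored full pattern.
oracle_scan_strand <- function(seq, base = "G", min_stems = 4L) {
  n <- nchar(seq)
  minlen <- 3L * min_stems + (min_stems - 1L)
  pat <- sprintf("^(?:%s{3,}[ACGTN]{1,7}){%d,}%s{3,}$", base, min_stems - 1L,
                 base)
  runs <- gregexpr(paste0(base, "+"), seq)[[1]]
  if (runs[1] == -1L) return(data.frame(start = integer(), end = integer()))
  rs <- as.integer(runs)
  re <- rs + attr(runs, "match.length") - 1L
  out_s <- integer(0); out_e <- integer(0)
  pos <- 1L
  while (pos <= n - minlen + 1L) {
    s <- pos
    found <- FALSE
    while (s <= n - minlen + 1L) {
      if (substr(seq, s, s + 2L) == strrep(base, 3L)) {
        k <- max(which(rs <= s))
        upper <- max_reach_from(s, k, rs, re)
        if (upper - s + 1L >= minlen) {
          for (len in (upper - s + 1L):minlen) {
            if (grepl(pat, substr(seq, s, s + len - 1L), perl = TRUE)) {
              out_s <- c(out_s, s); out_e <- c(out_e, s + len - 1L)
              pos <- s + len
              found <- TRUE
              break
            }
          }
        }
      }
      if (found) break
      s <- s + 1L
    }
    if (!found) break
  }
  data.frame(start = out_s - 1L, end = out_e)  # 0-based half-open
}

# Upper bound on the end of any match starting at s (inside run k): walk
# forward over runs while the pure inter-run gap is at most 7 (a loop can
# never bridge more than 7 consecutive non-base characters).
max_reach_from <- function(s, k, rs, re) {
  end <- re[k]
  j <- k
  while (j + 1L <= length(rs) && rs[j + 1L] - re[j] - 1L <= 7L) {
    j <- j + 1L
    end <- re[j]
  }
  end
}

oracle_scan_both <- function(seq, min_stems = 4L) {
  fwd <- oracle_scan_strand(seq, "G", min_stems)
  rev <- oracle_scan_strand(seq, "C", min_stems)
  fwd$strand <- rep("+", nrow(fwd))
  rev$strand <- rep("-", nrow(rev))
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exhaustive maximal-stem count: plain recursion over all decompositions.
oracle_count_stems <- function(motif_seq, max_loop = 7L) {
  n <- nchar(motif_seq)
  ch <- strsplit(motif_seq, "", fixed = TRUE)[[1]]
  best <- -Inf
  recurse <- function(pos, stems) {
    if (pos > n) return()
    g <- 0L
    while (pos + g <= n && ch[pos + g] == "G") g <- g + 1L
    if (g < 3L) return()
    for (use in 3L:g) {
      if (pos + use - 1L == n) best <<- max(best, stems + 1L)
      for (l in 1L:max_loop) {
        np <- pos + use + l
        if (np <= n) recurse(np, stems + 1L)
      }
    }
  }
  recurse(1L, 0L)
  if (is.finite(best)) best else NA_integer_
}

# Brute-force merged imperfect motif intervals (0-based half-open) for one
# strand; stems found by direct position-wise checking, chains by explicit
# successor nesting (first three links explicit, then any-length extension).
oracle_imperfect_merged_strand <- function(seq, base, params) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_b <- ch == base
  stems <- list()
  for (s in seq_len(n)) {
    # contiguous stems
    for (L in params$stem_min:params$stem_max) {
      e <- s + L - 1L
      if (e <= n && all(is_b[s:e])) stems[[length(stems) + 1L]] <- c(s, e)
    }
    # bulged stems: l1 Gs, bulge 1..max_bulge_len non-G, l2 Gs
    for (l1 in 1L:(params$stem_max - 1L)) {
      for (bl in 1L:params$max_bulge_len) {
        for (l2 in 1L:(params$stem_max - 1L)) {
          tot <- l1 + l2
          if (tot < params$stem_min || tot > params$stem_max) next
          e <- s + l1 + bl + l2 - 1L
          if (e > n) next
          blk1 <- s:(s + l1 - 1L)
          bulge <- (s + l1):(s + l1 + bl - 1L)
          blk2 <- (s + l1 + bl):e
          if (all(is_b[blk1]) && all(!is_b[bulge]) && all(is_b[blk2])) {
            stems[[length(stems) + 1L]] <- c(s, e)
          }
        }
      }
    }
  }
  stems <- unique(stems)
  if (!length(stems)) return(data.frame(start = integer(), end = integer()))
  S <- vapply(stems, `[`, integer(1), 1L)
  E <- vapply(stems, `[`, integer(1), 2L)
  succ <- function(i) which(S >= E[i] + 2L & S <= E[i] + 1L + params$max_loop)
  # max end over chains of any length starting at stem i
  memo <- rep(NA_real_, length(S))
  maxend <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    memo[i] <<- E[i]  # guard against cycles (none possible, but safe)
    v <- succ(i)
    best <- E[i]
    for (j in v) best <- max(best, maxend(j))
    memo[i] <<- best
    best
  }
  spans_s <- integer(0); spans_e <- integer(0)
  for (i1 in seq_along(S)) {
    for (i2 in succ(i1)) {
      for (i3 in succ(i2)) {
        for (i4 in succ(i3)) {
          spans_s <- c(spans_s, S[i1])
          spans_e <- c(spans_e, maxend(i4))
        }
      }
    }
  }
  if (!length(spans_s)) return(data.frame(start = integer(), end = integer()))
  o <- order(spans_s, spans_e)
  spans_s <- spans_s[o]; spans_e <- spans_e[o]
  # union with book-ended merging
  ms <- spans_s[1]; me <- spans_e[1]
  us <- integer(0); ue <- integer(0)
  for (i in seq_along(spans_s)[-1]) {
    if (spans_s[i] <= me + 1L) {
      me <- max(me, spans_e[i])
    } else {
      us <- c(us, ms); ue <- c(ue, me)
      ms <- spans_s[i]; me <- spans_e[i]
    }
  }
  us <- c(us, ms); ue <- c(ue, me)
  data.frame(start = us - 1L, end = ue)
}

oracle_imperfect_merged <- function(seq, params) {
  fwd <- oracle_imperfect_merged_strand(seq, "G", params)
  rev <- oracle_imperfect_merged_strand(seq, "C", params)
  fwd$strand <- rep("+", nrow(fwd))
  rev$strand <- rep("-", nrow(rev))
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  d <- as.numeric(d)
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

hyper_upper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Naive all-pairs interval overlap on 0-based half-open tables.
naive_overlaps <- function(q, s) {
  out <- NULL
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j] && q$start[i] < s$end[j] &&
          q$end[i] > s$start[j]) {
        out <- rbind(out, data.frame(qi = i, si = j))
      }
    }
  }
  if (is.null(out)) data.frame(qi = integer(), si = integer()) else out
}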