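# Independent oracles, deliberately coded without reference to the package
# internals: naive scans, literal greedy transcriptions, exhaustive
# enumerations and direct formula evaluations.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]),
        collapse = "")
}

# Naive O(n*m) exact-placement scan over both strands.
oracle_scan_map <- function(read, genome_df) {
  hits <- list()
  for (ci in seq_len(nrow(genome_df))) {
    g <- genome_df$seq[ci]
    L <- nchar(read)
    for (s in seq_len(nchar(g) - L + 1L)) {
      seg <- substr(g, s, s + L - 1L)
      if (seg == read) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = genome_df$id[ci], start = s - 1L, end = s - 1L + L,
          strand = "+")
      }
      if (seg == oracle_revcomp(read)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = genome_df$id[ci], start = s - 1L, end = s - 1L + L,
          strand = "-")
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# Literal transcription of the greedy clustering steps (i)-(v): sort reads
# by count; most frequent founds cluster 1 with its own coordinates; each
# later read joins the first same-strand cluster whose flanked window
# contains it, else opens a new cluster.
oracle_cluster <- function(aln, up_flank = 3L, down_flank = 5L) {
  ord <- order(-aln$total, aln$chrom, aln$start, aln$strand, aln$seq)
  aln <- aln[ord, , drop = FALSE]
  clusters <- list()
  assign <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    placed <- FALSE
    for (j in seq_along(clusters)) {
      cl <- clusters[[j]]
      ws <- if (cl$strand == "+") cl$start - up_flank else
        cl$start - down_flank
      we <- if (cl$strand == "+") cl$end + down_flank else
        cl$end + up_flank
      if (cl$chrom == aln$chrom[i] && cl$strand == aln$strand[i] &&
            aln$start[i] >= ws && aln$end[i] <= we) {
        assign[i] <- j
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        chrom = aln$chrom[i], start = aln$start[i], end = aln$end[i],
        strand = aln$strand[i])
      assign[i] <- length(clusters)
    }
  }
  list(aln = aln, assign = assign,
       founders = do.call(rbind, lapply(clusters, as.data.frame)))
}

# Exhaustive maximum over all nested structures with hairpin loops of at
# least min_loop unpaired positions (plain recursion, no memoisation).
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) +
                      if (k < j) rec(k + 1L, j) else 0L)
      }
    }
    best
  }
  if (length(ch) < 2) return(0L)
  rec(1L, length(ch))
}

# Two-sided Fisher exact p by brute-force hypergeometric tail summation.
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (greater) Fisher exact p by tail summation.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  hi <- min(k, m)
  x <- a:hi
  sum(exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)))
}

# Direct product-moment formula.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive enumeration of banded <=1-gap antiparallel alignments of a
# miRNA against a window; returns the minimum expectation score.
oracle_min_expectation <- function(mirna, window, hspsize = 20L,
                                   seed = c(2L, 13L), gap_pen = 2) {
  mir <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  sc <- rev(strsplit(toupper(chartr("U", "T", window)), "")[[1]])
  m <- length(mir); w <- length(sc)
  wt <- function(p) if (p > hspsize) 0 else if (p >= seed[1] && p <= seed[2]) 2 else 1
  pen <- function(a, b) {
    pr <- paste0(a, b)
    if (pr %in% c("AT", "TA", "CG", "GC")) 0
    else if (pr %in% c("GT", "TG")) 0.5 else 1
  }
  scores <- numeric(0)
  if (w == m) {
    scores <- c(scores, sum(vapply(seq_len(m), function(i)
      pen(mir[i], sc[i]) * wt(i), numeric(1))))
  }
  if (w == m - 1L) {
    for (g in seq_len(m)) {  # miRNA base g bulged
      s <- gap_pen * wt(g)
      for (i in seq_len(m)) {
        if (i == g) next
        j <- if (i < g) i else i - 1L
        s <- s + pen(mir[i], sc[j]) * wt(i)
      }
      scores <- c(scores, s)
    }
  }
  if (w == m + 1L) {
    for (g in seq_len(m + 1L)) {  # site base bulged after miRNA pos g-1
      s <- gap_pen * wt(g)
      for (i in seq_len(m)) {
        j <- if (i < g) i else i + 1L
        s <- s + pen(mir[i], sc[j]) * wt(i)
      }
      scores <- c(scores, s)
    }
  }
  if (!length(scores)) return(Inf)
  min(scores)
}
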