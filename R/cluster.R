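# Greedy positional read clustering and pairing of arm clusters into
# hairpin candidates.
#
# The clustering pass: reads sorted by count; the most frequent read
# founds the first cluster (cluster coordinates are the founder's
# coordinates); every later read joins the first existing same-strand
# cluster whose flanked window fully contains it, else founds a new
# cluster. The window extends the founder 3 nt upstream and 5 nt
# downstream in strand orientation so isomiRs join their arm's cluster.

#' Cluster aligned reads greedily by position
#'
#' @param alignments data.frame from [map_exact()] or [read_sam_min()] with
#'   columns `seq`, `total`, `chrom`, `start`, `end`, `strand`.
#' @param up_flank,down_flank Window flanks (nt) added before the founder
#'   start and after the founder end, in strand orientation: plus-strand
#'   windows are `[start - up_flank, end + down_flank)`, minus-strand
#'   windows `[start - down_flank, end + up_flank)`.
#' @return list with `clusters` (one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end` = founder coordinates, `window_start`, `window_end`,
#'   `strand`, `founder_seq`, `total_count`, `n_members`) and `members`
#'   (the input alignments in processing order with a `cluster_id` column).
#' @export
cluster_reads <- function(alignments, up_flank = 3L, down_flank = 5L) {
  stopifnot(up_flank >= 0, down_flank >= 0)
  aln <- alignments[order(-alignments$total, alignments$chrom,
                          alignments$start, alignments$strand,
                          alignments$seq), , drop = FALSE]
  rownames(aln) <- NULL
  n <- nrow(aln)
  cl_chrom <- character(0); cl_strand <- character(0)
  cl_ws <- integer(0); cl_we <- integer(0)
  cl_start <- integer(0); cl_end <- integer(0)
  cl_founder <- character(0); cl_total <- integer(0); cl_n <- integer(0)
  member_of <- integer(n)
  for (i in seq_len(n)) {
    s <- aln$start[i]; e <- aln$end[i]
    hit <- which(cl_chrom == aln$chrom[i] & cl_strand == aln$strand[i] &
                   cl_ws <= s & e <= cl_we)
    if (length(hit)) {
      j <- hit[1]  # first existing cluster in creation order
      cl_total[j] <- cl_total[j] + aln$total[i]
      cl_n[j] <- cl_n[j] + 1L
      member_of[i] <- j
    } else {
      j <- length(cl_chrom) + 1L
      cl_chrom[j] <- aln$chrom[i]; cl_strand[j] <- aln$strand[i]
      cl_start[j] <- s; cl_end[j] <- e
      if (aln$strand[i] == "+") {
        cl_ws[j] <- s - up_flank; cl_we[j] <- e + down_flank
      } else {
        cl_ws[j] <- s - down_flank; cl_we[j] <- e + up_flank
      }
      cl_founder[j] <- aln$seq[i]
      cl_total[j] <- aln$total[i]; cl_n[j] <- 1L
      member_of[i] <- j
    }
  }
  clusters <- data.frame(
    cluster_id = sprintf("cl%04d", seq_along(cl_chrom)),
    chrom = cl_chrom, start = cl_start, end = cl_end,
    window_start = cl_ws, window_end = cl_we, strand = cl_strand,
    founder_seq = cl_founder, total_count = cl_total, n_members = cl_n,
    stringsAsFactors = FALSE)
  members <- aln
  members$cluster_id <- clusters$cluster_id[member_of]
  list(clusters = clusters, members = members)
}

#' Pair arm clusters into hairpin candidates
#'
#' Every same-chromosome, same-strand cluster pair whose founder intervals
#' are separated by a gap of at least 0 and strictly less than
#' `max_pair_gap` nt is eligible: a bona fide pre-miRNA leaves two read
#' clusters, one per processed arm. Each cluster joins at most one
#' candidate; pairing is greedy by smallest gap, with ties resolved towards
#' the genomically left partner. Overlapping clusters (negative gap) are
#' never paired and are tallied. The mature arm is the cluster with the
#' higher total count (tie: the upstream arm) and contributes its founder
#' sequence as the mature miRNA; the other founder is the star.
#'
#' @param clusters Cluster table from [cluster_reads()].
#' @param max_pair_gap Strict upper bound on the inter-cluster gap (nt).
#' @return data.frame of candidates: ids of both arm clusters, gap, mature
#'   and star cluster ids/sequences/coordinates, precursor interval
#'   (union of both windows plus the gap), chrom and strand. Attribute
#'   `n_overlapping_pairs` tallies pairs rejected for negative gap.
#' @export
pair_clusters <- function(clusters, max_pair_gap = 150L) {
  cand <- list(); n_overlap <- 0L
  pairs <- list()
  if (nrow(clusters) >= 2) {
    key <- paste(clusters$chrom, clusters$strand)
    for (grp in unique(key)) {
      idx <- which(key == grp)
      if (length(idx) < 2) next
      idx <- idx[order(clusters$start[idx])]
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          up <- idx[a]; dn <- idx[b]
          gap <- clusters$start[dn] - clusters$end[up]
          if (gap < 0) { n_overlap <- n_overlap + 1L; next }
          if (gap < max_pair_gap) {
            pairs[[length(pairs) + 1L]] <- data.frame(
              up = up, dn = dn, gap = gap,
              up_start = clusters$start[up], dn_start = clusters$start[dn])
          }
        }
      }
    }
  }
  if (length(pairs)) {
    p <- do.call(rbind, pairs)
    p <- p[order(p$gap, p$up_start, p$dn_start), , drop = FALSE]
    used <- rep(FALSE, nrow(clusters))
    for (i in seq_len(nrow(p))) {
      up <- p$up[i]; dn <- p$dn[i]
      if (used[up] || used[dn]) next
      used[up] <- used[dn] <- TRUE
      a <- clusters[up, ]; b <- clusters[dn, ]
      mature_is_up <- a$total_count >= b$total_count
      m <- if (mature_is_up) a else b
      s <- if (mature_is_up) b else a
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = a$chrom, strand = a$strand,
        arm_a = a$cluster_id, arm_b = b$cluster_id, gap = p$gap[i],
        mature_cluster = m$cluster_id, star_cluster = s$cluster_id,
        mature_seq = m$founder_seq, star_seq = s$founder_seq,
        mature_start = m$start, mature_end = m$end,
        star_start = s$start, star_end = s$end,
        mature_count = m$total_count, star_count = s$total_count,
        precursor_start = min(a$window_start, b$window_start),
        precursor_end = max(a$window_end, b$window_end),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(cand)) do.call(rbind, cand) else data.frame(
    chrom = character(), strand = character(), arm_a = character(),
    arm_b = character(), gap = integer(), mature_cluster = character(),
    star_cluster = character(), mature_seq = character(),
    star_seq = character(), mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(), mature_count = integer(),
    star_count = integer(), precursor_start = integer(),
    precursor_end = integer())
  if (nrow(out)) {
    out <- out[order(out$chrom, out$precursor_start, out$strand), ,
               drop = FALSE]
    out <- cbind(candidate_id = sprintf("cand%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
  } else {
    out <- cbind(candidate_id = character(0), out)
  }
  attr(out, "n_overlapping_pairs") <- n_overlap
  out
}

#' Filter candidates by mature miRNA length
#'
#' Keeps candidates whose mature sequence length lies in
#' `[len_min, len_max]` (inclusive on both sides).
#'
#' @param candidates Candidate table from [pair_clusters()].
#' @param len_min,len_max Inclusive mature-length bounds (nt).
#' @return Filtered candidate table; attribute `n_dropped_length` tallies
#'   rejections.
#' @export
filter_candidate_length <- function(candidates, len_min = 20L,
                                    len_max = 24L) {
  len <- nchar(candidates$mature_seq)
  keep <- len >= len_min & len <= len_max
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_length") <- sum(!keep)
  out
}

#' Quantify candidate mature arms per library
#'
#' The mature count of a candidate in a library is the sum of the
#' per-library counts of all member reads of its mature arm cluster.
#' Candidates containing more than one placement of the same read sequence
#' are flagged `multi_placement`.
#'
#' @param candidates Candidate table from [pair_clusters()].
#' @param clustering list from [cluster_reads()] (`members` is used).
#' @param unique_reads Collapsed read table from [collapse_unique()] whose
#'   per-library count columns define the libraries.
#' @return list with `counts` (integer matrix, candidates x libraries) and
#'   `flags` (data.frame: `candidate_id`, `multi_placement`).
#' @export
quantify <- function(candidates, clustering, unique_reads) {
  lib_names <- setdiff(colnames(unique_reads), c("seq", "total"))
  counts <- matrix(0L, nrow(candidates), length(lib_names),
                   dimnames = list(candidates$candidate_id, lib_names))
  multi <- logical(nrow(candidates))
  members <- clustering$members
  seq_counts <- as.matrix(unique_reads[, lib_names, drop = FALSE])
  rownames(seq_counts) <- unique_reads$seq
  for (i in seq_len(nrow(candidates))) {
    mem_m <- members[members$cluster_id == candidates$mature_cluster[i], ]
    mem_all <- members[members$cluster_id %in%
                         c(candidates$mature_cluster[i],
                           candidates$star_cluster[i]), ]
    multi[i] <- anyDuplicated(mem_all$seq) > 0
    if (nrow(mem_m)) {
      counts[i, ] <- as.integer(
        colSums(seq_counts[mem_m$seq, , drop = FALSE]))
    }
  }
  list(counts = counts,
       flags = data.frame(candidate_id = candidates$candidate_id,
                          multi_placement = multi,
                          stringsAsFactors = FALSE))
}
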