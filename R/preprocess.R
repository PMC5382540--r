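# Read preprocessing: 3' adapter trimming, size/contaminant filtering,
# collapsing to unique reads, and exact placement on the genome.

#' Trim a 3' adapter from reads
#'
#' Primitive 3'-adapter cleaning: the read is cut at the leftmost position
#' where a prefix of the adapter aligns exactly, provided the aligned
#' adapter segment is at least `min_overlap` nt long (a full internal
#' adapter occurrence always qualifies). Everything from the trim point to
#' the 3' end is removed. Reads without a qualifying adapter hit are
#' returned unchanged and flagged untrimmed.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix length at the trim point.
#' @return data.frame with columns `seq` (trimmed) and `trimmed` (logical).
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 8L) {
  stopifnot(min_overlap >= 1)
  adapter <- dna_norm(adapter)
  la <- nchar(adapter)
  probe_len <- min(min_overlap, la)
  probe <- substr(adapter, 1L, probe_len)
  seqs_n <- dna_norm(seqs)
  L <- nchar(seqs_n)
  cut <- rep(NA_integer_, length(seqs_n))
  # Any qualifying hit starts with the first probe_len adapter bases, so the
  # candidate trim points are the occurrences of that probe.
  hits <- gregexpr(probe, seqs_n, fixed = TRUE)
  for (r in seq_along(seqs_n)) {
    pos <- hits[[r]]
    if (pos[1] == -1L) next
    for (p in pos) {
      seg_len <- min(la, L[r] - p + 1L)
      if (seg_len < probe_len) break
      if (substr(seqs_n[r], p, p + seg_len - 1L) ==
          substr(adapter, 1L, seg_len)) {
        cut[r] <- p
        break
      }
    }
  }
  trimmed <- !is.na(cut)
  out <- seqs_n
  out[trimmed] <- substr(seqs_n[trimmed], 1L, cut[trimmed] - 1L)
  data.frame(seq = out, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Size- and contaminant-filter reads
#'
#' Applies, in order: (1) the size selection `[len_min, len_max]`;
#' (2) removal of reads that occur as an exact substring of any contaminant
#' sequence on either strand (a conservative stand-in for alignment against
#' rRNA/tRNA/repeat databases). Per-filter tallies are reported in
#' application order.
#'
#' @param seqs Character vector of trimmed read sequences.
#' @param len_min,len_max Inclusive length bounds.
#' @param contaminants Optional data.frame from [read_fasta()] with
#'   contaminant ncRNA sequences.
#' @return list with `kept` (character vector) and `tally` (named integer
#'   vector: input, dropped_length, dropped_contaminant, kept).
#' @export
filter_reads <- function(seqs, len_min = 18L, len_max = 30L,
                         contaminants = NULL) {
  seqs <- dna_norm(seqs)
  n_in <- length(seqs)
  len_ok <- nchar(seqs) >= len_min & nchar(seqs) <= len_max
  n_len <- sum(!len_ok)
  seqs <- seqs[len_ok]
  n_cont <- 0L
  if (!is.null(contaminants) && nrow(contaminants) > 0 && length(seqs)) {
    haystack <- paste(c(dna_norm(contaminants$seq),
                        revcomp(contaminants$seq)), collapse = "#")
    uniq <- unique(seqs)
    is_cont <- vapply(uniq, function(s) grepl(s, haystack, fixed = TRUE),
                      logical(1))
    drop <- seqs %in% uniq[is_cont]
    n_cont <- sum(drop)
    seqs <- seqs[!drop]
  }
  list(kept = seqs,
       tally = c(input = n_in, dropped_length = n_len,
                 dropped_contaminant = n_cont, kept = length(seqs)))
}

#' Collapse reads to unique sequences with per-library counts
#'
#' @param seqs Character vector of kept read sequences (all libraries).
#' @param lib_index Integer vector, the 1-based library index of each read.
#' @param lib_names Library labels; determines the count columns and the
#'   number of libraries.
#' @return data.frame with columns `seq`, `total`, then one count column per
#'   library, sorted by `total` descending with ties broken by sequence
#'   (lexicographic ascending).
#' @export
collapse_unique <- function(seqs, lib_index, lib_names) {
  stopifnot(length(seqs) == length(lib_index))
  n_lib <- length(lib_names)
  if (!length(seqs)) {
    out <- data.frame(seq = character(), total = integer())
    for (nm in lib_names) out[[nm]] <- integer()
    return(out)
  }
  stopifnot(all(lib_index >= 1), all(lib_index <= n_lib))
  fs <- factor(seqs)
  counts <- matrix(0L, nlevels(fs), n_lib,
                   dimnames = list(levels(fs), lib_names))
  tab <- table(fs, factor(lib_index, levels = seq_len(n_lib)))
  counts[, ] <- as.integer(tab)
  total <- as.integer(rowSums(counts))
  ord <- order(-total, levels(fs))
  out <- data.frame(seq = levels(fs)[ord], total = total[ord],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts[ord, , drop = FALSE],
                                  row.names = seq_along(ord)))
  out
}

# Genome as a cached DNAStringSet for exact matching.
genome_stringset <- function(genome) {
  Biostrings::DNAStringSet(stats::setNames(dna_norm(genome$seq), genome$id))
}

#' Place unique reads on the genome by exact matching
#'
#' Reports every exact, ungapped, full-length placement of each unique read
#' on both strands. Minus-strand placements store the genome-forward
#' interval with strand `-` and the read sequence in as-sequenced
#' orientation. Multi-mapped reads are retained at all placements, each
#' carrying `n_placements`. Reads with no placement are dropped and tallied.
#'
#' @param unique_reads data.frame from [collapse_unique()].
#' @param genome data.frame from [read_fasta()] (`id`, `seq`).
#' @return data.frame of alignments: `seq`, `total`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `n_placements`; attribute
#'   `n_unplaced` counts dropped unique reads.
#' @export
map_exact <- function(unique_reads, genome) {
  gset <- genome_stringset(genome)
  n <- nrow(unique_reads)
  hit_rows <- list()
  n_hits <- integer(n)
  widths <- nchar(unique_reads$seq)
  # Constant-width pattern dictionaries give fast simultaneous matching of
  # all reads of one length; both strands are searched on the forward genome.
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(unique_reads$seq[idx])
    rc <- Biostrings::reverseComplement(fwd)
    pd <- Biostrings::PDict(c(fwd, rc))
    for (ci in seq_along(gset)) {
      m <- Biostrings::matchPDict(pd, gset[[ci]])
      starts <- Biostrings::startIndex(m)
      hit_pat <- which(lengths(starts) > 0)
      for (pi in hit_pat) {
        r <- idx[if (pi > length(idx)) pi - length(idx) else pi]
        strand <- if (pi > length(idx)) "-" else "+"
        st <- starts[[pi]]
        n_hits[r] <- n_hits[r] + length(st)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          r = r, chrom = names(gset)[ci], start = st - 1L,
          end = st - 1L + w, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  n_unplaced <- sum(n_hits == 0)
  out <- do.call(rbind, hit_rows)
  if (!is.null(out)) {
    out$seq <- unique_reads$seq[out$r]
    out$total <- unique_reads$total[out$r]
    out$n_placements <- n_hits[out$r]
    # stable, read-major order (reads in collapse_unique order)
    out <- out[order(out$r, out$chrom, out$start, out$strand), ]
    out$r <- NULL
  }
  if (is.null(out)) {
    out <- data.frame(seq = character(), total = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), n_placements = integer())
  } else {
    out <- out[, c("seq", "total", "chrom", "start", "end", "strand",
                   "n_placements")]
    rownames(out) <- NULL
  }
  attr(out, "n_unplaced") <- n_unplaced
  out
}
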