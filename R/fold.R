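# Structural screen of candidate precursors. A base-pair-maximisation fold
# (Nussinov dynamic programme over Watson-Crick + G:U pairs) scores each
# precursor; hairpin_check then asks whether the mature arm is pairing into
# the star half of a single-loop stem. This is a pass/fail structural
# plausibility screen, not a thermodynamic model; externally computed
# dot-bracket structures can be supplied instead for real data.

# TRUE where two bases can pair (Watson-Crick or G:U wobble).
can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Fold a sequence by base-pair maximisation
#'
#' Nussinov dynamic programme maximising the number of nested Watson-Crick
#' plus G:U pairs, with a minimum hairpin loop of `min_loop` unpaired
#' positions (a pair `(i, j)` requires `j - i > min_loop`). The traceback is
#' deterministic: at each interval the 5' base prefers pairing with the
#' 3'-most partner that preserves optimality.
#'
#' @param seq Nucleotide string (1 to 500 nt; T and U equivalent).
#' @param min_loop Minimum number of unpaired positions enclosed by a pair.
#' @return list of class `saltmir_fold`: `seq`, `structure` (dot-bracket),
#'   `pairs` (two-column matrix of 1-based indices, i < j), `n_pairs`.
#' @examples
#' fold_maxpair("GGGAAACCC")$structure
#' @export
fold_maxpair <- function(seq, min_loop = 3L) {
  s <- dna_norm(seq)
  n <- nchar(s)
  stopifnot(n >= 1, n <= 500)
  ch <- seq_chars(s)
  pairmat <- outer(ch, ch, can_pair)
  # M[i, j]: max pairs in s[i..j]; padded row n+1 supplies empty suffixes.
  M <- matrix(0L, n + 1L, n)
  if (n > min_loop + 1L) {
    for (i in (n - min_loop - 1L):1L) {
      for (j in (i + min_loop + 1L):n) {
        best <- M[i + 1L, j]
        ks <- (i + min_loop + 1L):j
        ks <- ks[pairmat[i, ks]]
        if (length(ks)) {
          left <- M[i + 1L, ks - 1L]
          right <- ifelse(ks < j, M[cbind(ks + 1L, j)], 0L)
          best <- max(best, 1L + left + right)
        }
        M[i, j] <- best
      }
    }
  }
  # Deterministic traceback: prefer pairing i with the largest admissible k.
  pairs <- matrix(integer(0), 0, 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i <= j && j - i > min_loop) {
      val <- M[i, j]
      if (val == 0L) break
      ks <- (i + min_loop + 1L):j
      ks <- rev(ks[pairmat[i, ks]])
      paired <- FALSE
      for (k in ks) {
        right <- if (k < j) M[k + 1L, j] else 0L
        if (1L + M[i + 1L, k - 1L] + right == val) {
          pairs <- rbind(pairs, c(i, k))
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  structure_chr <- rep(".", n)
  if (nrow(pairs)) {
    structure_chr[pairs[, 1]] <- "("
    structure_chr[pairs[, 2]] <- ")"
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  res <- list(seq = s, structure = paste(structure_chr, collapse = ""),
              pairs = pairs, n_pairs = nrow(pairs))
  class(res) <- "saltmir_fold"
  res
}

#' Parse a dot-bracket structure into a fold object
#'
#' Entry point for externally computed secondary structures (e.g. from a
#' thermodynamic folder): converts a dot-bracket string into the same
#' object [fold_maxpair()] produces, so [hairpin_check()] can consume it.
#'
#' @param seq Sequence the structure belongs to.
#' @param structure Dot-bracket string of the same length, balanced.
#' @return list of class `saltmir_fold`.
#' @export
parse_dotbracket <- function(seq, structure) {
  stopifnot(nchar(seq) == nchar(structure))
  ch <- seq_chars(structure)
  if (!all(ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  res <- list(seq = dna_norm(seq), structure = structure, pairs = pairs,
              n_pairs = nrow(pairs))
  class(res) <- "saltmir_fold"
  res
}

# Number of terminal (innermost) loops in a dot-bracket string.
count_terminal_loops <- function(structure) {
  length(gregexpr("\\(\\.*\\)", structure)[[1]]) -
    (gregexpr("\\(\\.*\\)", structure)[[1]][1] == -1L)
}

#' Structural plausibility check for a hairpin candidate
#'
#' Passes a candidate iff, after pruning helices shorter than `min_helix`
#' stacked pairs (base-pair maximisation scatters spurious isolated pairs
#' over loops and flanks; lonely-pair pruning removes them), (a) at least
#' `min_mature_paired_frac` of mature positions are paired, (b) every
#' paired mature position partners into the star half of the precursor
#' (the far side of the stem), and (c) the structure has exactly one
#' terminal loop. The numeric criteria are explicit artifact choices
#' (a pass/fail screen); the metrics are reported regardless of the
#' verdict.
#'
#' @param fold `saltmir_fold` object for the precursor sequence, oriented
#'   5' to 3' on the candidate strand.
#' @param mature_range Integer pair: 1-based inclusive positions of the
#'   mature miRNA within the precursor (strand orientation).
#' @param min_mature_paired_frac Minimum fraction of paired mature bases.
#' @param min_helix Minimum stacked-pair run length retained. Helices of
#'   fewer than 4 stacked pairs are structurally marginal in pre-miRNA
#'   stems; pruning them sharpens the screen's specificity on random
#'   sequence without touching genuine stems.
#' @return list: `pass`, `paired_frac`, `partners_in_star_half`, `n_loops`.
#' @export
hairpin_check <- function(fold, mature_range, min_mature_paired_frac = 0.6,
                          min_helix = 4L) {
  stopifnot(length(mature_range) == 2, mature_range[1] <= mature_range[2])
  n <- nchar(fold$seq)
  mat_pos <- mature_range[1]:mature_range[2]
  pairs <- prune_helices(fold$pairs, min_helix)
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  paired <- !is.na(partner[mat_pos])
  paired_frac <- mean(paired)
  # The star half is the precursor side across the loop from the mature arm.
  mid <- (n + 1) / 2
  mature_is_5p <- mean(mat_pos) <= mid
  partners <- partner[mat_pos][paired]
  in_star_half <- if (!length(partners)) FALSE else {
    if (mature_is_5p) all(partners > mid) else all(partners < mid)
  }
  pruned_structure <- rep(".", n)
  if (nrow(pairs)) {
    pruned_structure[pairs[, 1]] <- "("
    pruned_structure[pairs[, 2]] <- ")"
  }
  n_loops <- count_terminal_loops(paste(pruned_structure, collapse = ""))
  pass <- paired_frac >= min_mature_paired_frac && in_star_half &&
    n_loops == 1L
  list(pass = pass, paired_frac = paired_frac,
       partners_in_star_half = in_star_half, n_loops = n_loops)
}

# Keep only pairs in stacked runs (helices) of at least min_helix pairs.
prune_helices <- function(pairs, min_helix = 3L) {
  if (is.null(pairs) || nrow(pairs) < 1 || min_helix <= 1) {
    return(pairs %||% matrix(integer(0), 0, 2))
  }
  p <- pairs[order(pairs[, 1]), , drop = FALSE]
  run <- integer(nrow(p))
  run[1] <- 1L
  for (k in seq_len(nrow(p))[-1]) {
    stacked <- p[k, 1] == p[k - 1, 1] + 1L && p[k, 2] == p[k - 1, 2] - 1L
    run[k] <- if (stacked) run[k - 1] else run[k - 1] + 1L
  }
  keep <- run %in% as.integer(names(which(table(run) >= min_helix)))
  p[keep, , drop = FALSE]
}

# Mature-arm position range within the precursor, strand oriented, 1-based
# inclusive; used by the pipeline to call hairpin_check on candidates.
mature_range_in_precursor <- function(candidate) {
  if (candidate$strand == "+") {
    c(candidate$mature_start - candidate$precursor_start + 1L,
      candidate$mature_end - candidate$precursor_start)
  } else {
    c(candidate$precursor_end - candidate$mature_end + 1L,
      candidate$precursor_end - candidate$mature_start)
  }
}

# Precursor sequence in strand orientation from the genome table.
precursor_seq <- function(candidate, genome) {
  g <- genome$seq[match(candidate$chrom, genome$id)]
  s <- substr(g, candidate$precursor_start + 1L, candidate$precursor_end)
  if (candidate$strand == "-") revcomp(s) else dna_norm(s)
}
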