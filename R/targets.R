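# Plant miRNA target-site scanning. A miRNA is aligned antiparallel against
# candidate transcript windows and scored with the canonical plant
# expectation penalty: match 0, G:U wobble 0.5, mismatch 1.0, gap 2.0, with
# penalties doubled in the seed region (miRNA positions 2-13) and positions
# beyond hspsize unscored. Sites are kept up to a maximum expectation, and
# a mismatch or gap in the central positions (9-11) classifies the site as
# translationally inhibited rather than cleaved.

# Penalty of pairing miRNA base mb against site (transcript) base sb,
# antiparallel: 0 complement, 0.5 G:U wobble, 1 otherwise.
base_penalty <- function(mb, sb) {
  ifelse((mb == "A" & sb == "T") | (mb == "T" & sb == "A") |
           (mb == "G" & sb == "C") | (mb == "C" & sb == "G"), 0,
         ifelse((mb == "G" & sb == "T") | (mb == "T" & sb == "G"), 0.5, 1))
}

# Positional weight: 0 beyond hspsize (unscored), doubled in the seed range.
pos_weight <- function(pos, hspsize = 20L, seed_range = c(2L, 13L)) {
  ifelse(pos > hspsize, 0,
         ifelse(pos >= seed_range[1] & pos <= seed_range[2], 2, 1))
}

#' Align a miRNA against one candidate target window
#'
#' Banded global alignment of the miRNA (5' to 3') against the antiparallel
#' target window, minimising the expectation score, with at most one
#' bulge (gap) and a band of +/-2 positions. The traceback is deterministic
#' and prefers match > wobble > mismatch > gap at equal cost.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param window Transcript site sequence, 5' to 3'.
#' @param hspsize Number of miRNA 5' positions scored.
#' @param seed_range Inclusive miRNA position range with doubled penalties.
#' @param gap_penalty Base penalty of a bulged position.
#' @param max_gaps Maximum number of bulges.
#' @return list of class `saltmir_duplex`: `mirna`, `window`, `expectation`
#'   (unrounded; `Inf` if no alignment exists within the band/gap budget)
#'   and `table`, one row per duplex column: `mir_pos` (NA for a target
#'   bulge), `pos_eff` (position used for weighting), `mir_base`,
#'   `site_base` (NA for a miRNA bulge), `state`
#'   (match/wobble/mismatch/gap_m/gap_t), `penalty`.
#' @export
align_duplex <- function(mirna, window, hspsize = 20L,
                         seed_range = c(2L, 13L), gap_penalty = 2,
                         max_gaps = 1L) {
  mir <- seq_chars(dna_norm(mirna))
  # site consumed from its 3' end: column j pairs mir[j] ungapped
  sc <- rev(seq_chars(dna_norm(window)))
  m <- length(mir); w <- length(sc)
  if (w == m) {
    # equal lengths admit only the ungapped alignment under a 1-gap budget
    pos <- seq_len(m)
    bp <- base_penalty(mir, sc)
    pen <- bp * pos_weight(pos, hspsize, seed_range)
    state <- ifelse(bp == 0, "match", ifelse(bp == 0.5, "wobble",
                                             "mismatch"))
    res <- list(mirna = paste(mir, collapse = ""), window = window,
                expectation = sum(pen),
                table = data.frame(mir_pos = pos, pos_eff = pos,
                                   mir_base = mir, site_base = sc,
                                   state = state, penalty = pen,
                                   column = pos, stringsAsFactors = FALSE))
    class(res) <- "saltmir_duplex"
    return(res)
  }
  band <- 2L
  wt <- function(pos) pos_weight(pos, hspsize, seed_range)
  INF <- Inf
  ng <- max_gaps + 1L
  D <- array(INF, dim = c(m + 1L, w + 1L, ng))
  MOVE <- array(NA_integer_, dim = c(m + 1L, w + 1L, ng))
  D[1, 1, 1] <- 0
  # moves: 1 pair, 2 gap_t (miRNA base bulged), 3 gap_m (site base bulged)
  for (i in 0:m) {
    for (j in 0:w) {
      if (abs(i - j) > band) next
      for (g in seq_len(ng)) {
        best <- INF; mv <- NA_integer_
        if (i > 0 && j > 0 && is.finite(D[i, j, g])) {
          cand <- D[i, j, g] + base_penalty(mir[i], sc[j]) * wt(i)
          if (cand < best) { best <- cand; mv <- 1L }
        }
        if (i > 0 && g > 1 && is.finite(D[i, j + 1, g - 1])) {
          cand <- D[i, j + 1, g - 1] + gap_penalty * wt(i)
          if (cand < best) { best <- cand; mv <- 2L }
        }
        if (j > 0 && g > 1 && is.finite(D[i + 1, j, g - 1])) {
          cand <- D[i + 1, j, g - 1] + gap_penalty * wt(i + 1)
          if (cand < best) { best <- cand; mv <- 3L }
        }
        if (best < D[i + 1, j + 1, g]) {
          D[i + 1, j + 1, g] <- best
          MOVE[i + 1, j + 1, g] <- mv
        }
      }
    }
  }
  finals <- D[m + 1, w + 1, ]
  res <- list(mirna = paste(mir, collapse = ""), window = window)
  class(res) <- "saltmir_duplex"
  if (!any(is.finite(finals))) {
    res$expectation <- Inf
    res$table <- data.frame(mir_pos = integer(), pos_eff = integer(),
                            mir_base = character(), site_base = character(),
                            state = character(), penalty = numeric())
    return(res)
  }
  g <- which.min(finals)
  res$expectation <- finals[g]
  # traceback
  i <- m; j <- w
  cols <- list()
  while (i > 0 || j > 0) {
    mv <- MOVE[i + 1, j + 1, g]
    if (mv == 1L) {
      pen <- base_penalty(mir[i], sc[j]) * wt(i)
      state <- if (base_penalty(mir[i], sc[j]) == 0) "match"
        else if (base_penalty(mir[i], sc[j]) == 0.5) "wobble" else "mismatch"
      cols[[length(cols) + 1L]] <- data.frame(
        mir_pos = i, pos_eff = i, mir_base = mir[i], site_base = sc[j],
        state = state, penalty = pen, stringsAsFactors = FALSE)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      cols[[length(cols) + 1L]] <- data.frame(
        mir_pos = i, pos_eff = i, mir_base = mir[i], site_base = NA_character_,
        state = "gap_t", penalty = gap_penalty * wt(i),
        stringsAsFactors = FALSE)
      i <- i - 1L; g <- g - 1L
    } else {
      cols[[length(cols) + 1L]] <- data.frame(
        mir_pos = NA_integer_, pos_eff = i + 1L, mir_base = NA_character_,
        site_base = sc[j], state = "gap_m",
        penalty = gap_penalty * wt(i + 1L), stringsAsFactors = FALSE)
      j <- j - 1L; g <- g - 1L
    }
  }
  tab <- do.call(rbind, rev(cols))
  tab$column <- seq_len(nrow(tab))
  res$table <- tab
  res
}

#' Expectation score of a duplex
#'
#' Sum of the per-column penalties, reported to one decimal. A perfect
#' duplex scores 0.0.
#'
#' @param duplex `saltmir_duplex` from [align_duplex()].
#' @return Numeric scalar (1 decimal).
#' @export
expectation_score <- function(duplex) {
  round(duplex$expectation, 1)
}

#' Classify the inhibition mode of a target site
#'
#' Translational inhibition iff any mismatch or gap falls in the central
#' miRNA positions (default 9-11, inclusive); otherwise cleavage.
#'
#' @param duplex `saltmir_duplex` from [align_duplex()].
#' @param central_range Inclusive miRNA position range.
#' @return `"translational"` or `"cleavage"`.
#' @export
classify_inhibition <- function(duplex, central_range = c(9L, 11L)) {
  tab <- duplex$table
  bad <- tab$state %in% c("mismatch", "gap_m", "gap_t") &
    tab$pos_eff >= central_range[1] & tab$pos_eff <= central_range[2]
  if (any(bad)) "translational" else "cleavage"
}

# Exact vectorised screen over all windows of one transcript: minimum
# expectation over the banded <=1-gap alignment space at every start, for
# window lengths m-1, m, m+1. Returns hits (a, w, score).
scan_windows <- function(mir, tseq, max_expectation, hspsize, seed_range,
                         gap_penalty) {
  m <- length(mir)
  tch <- seq_chars(tseq)
  n <- length(tch)
  if (n < m) return(NULL)
  wt <- pos_weight(seq_len(m), hspsize, seed_range)
  # pen[i, t]: penalty of miRNA position i against transcript base t
  pen <- matrix(0, m, n)
  for (i in seq_len(m)) pen[i, ] <- base_penalty(mir[i], tch) * wt[i]
  X <- n - m + 2L
  # Q[i, x] = pen[i, x + m - i]; entries outside the transcript are set to 0
  # and every formula below restricts its range so they are never used.
  Q <- matrix(0, m, X)
  for (i in seq_len(m)) {
    tt <- seq_len(X) + m - i
    ok <- tt >= 1 & tt <= n
    Q[i, ok] <- pen[i, tt[ok]]
  }
  C <- apply(Q, 2, cumsum)
  if (m == 1) C <- matrix(C, nrow = 1)
  Crow <- function(k, x) if (k == 0) rep(0, length(x)) else C[k, x]
  gapcost <- function(pos) gap_penalty * pos_weight(pos, hspsize, seed_range)
  hits <- list()
  add_hits <- function(a, score, w) {
    keep <- score <= max_expectation + 1e-9
    if (any(keep)) {
      hits[[length(hits) + 1L]] <<- data.frame(a = a[keep], w = w,
                                               score = score[keep])
    }
  }
  # ungapped, window length m
  a0 <- seq_len(n - m + 1L)
  add_hits(a0, C[m, a0], m)
  # one miRNA bulge at position g, window length m-1
  if (m >= 2 && n >= m - 1) {
    for (g in seq_len(m)) {
      if (g == 1) {
        a <- seq_len(min(X, n - (m - 1) + 1L))
        sc <- C[m, a] - C[1, a] + gapcost(1L)
      } else {
        a <- 2:min(X, n - (m - 1) + 1L)
        if (!length(a) || a[1] > a[length(a)]) next
        sc <- Crow(g - 1L, a - 1L) + C[m, a] - C[g, a] + gapcost(g)
      }
      add_hits(a, sc, m - 1L)
    }
  }
  # one site bulge after miRNA position g-1, window length m+1
  if (n >= m + 1) {
    for (g in seq_len(m + 1L)) {
      a <- seq_len(n - m)
      sc <- Crow(g - 1L, a + 1L) + C[m, a] - Crow(g - 1L, a) + gapcost(g)
      add_hits(a, sc, m + 1L)
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  # best score per (a, w)
  h <- h[order(h$a, h$w, h$score), , drop = FALSE]
  h[!duplicated(h[, c("a", "w")]), , drop = FALSE]
}

#' Scan transcripts for target sites of a miRNA
#'
#' Slides the miRNA over every window of the transcript (window lengths
#' within one bulge of the miRNA length), computes the minimum expectation
#' alignment at each position, and emits sites scoring at most
#' `max_expectation`. Overlapping sites on a transcript are merged keeping
#' the lower expectation; sites are sorted by expectation then position and
#' at most `max_sites` are reported per miRNA across the transcriptome.
#' Accessibility flanks (default 17 nt upstream, 13 nt downstream,
#' truncated at transcript ends) are attached to each site.
#'
#' @param mirna_id,mirna miRNA identifier and sequence (5' to 3').
#' @param transcripts data.frame from [read_fasta()] (`id`, `seq`).
#' @param max_expectation Maximum expectation of an emitted site.
#' @param hspsize,seed_range,gap_penalty See [align_duplex()].
#' @param central_range See [classify_inhibition()].
#' @param flank_up,flank_down Flank lengths (nt).
#' @param max_sites Cap on reported sites per miRNA.
#' @return data.frame: `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end` (0-based half-open on the transcript), `expectation`
#'   (1 decimal), `mode`, `flank_up_seq`, `flank_down_seq`.
#' @export
scan_transcript <- function(mirna_id, mirna, transcripts,
                            max_expectation = 2.0, hspsize = 20L,
                            seed_range = c(2L, 13L), gap_penalty = 2,
                            central_range = c(9L, 11L),
                            flank_up = 17L, flank_down = 13L,
                            max_sites = 200L) {
  mir <- seq_chars(dna_norm(mirna))
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- dna_norm(transcripts$seq[ti])
    n <- nchar(tseq)
    h <- scan_windows(mir, tseq, max_expectation, hspsize, seed_range,
                      gap_penalty)
    if (is.null(h)) next
    rows <- list()
    for (k in seq_len(nrow(h))) {
      a <- h$a[k]; w <- h$w[k]
      win <- substr(tseq, a, a + w - 1L)
      dup <- align_duplex(mirna, win, hspsize, seed_range, gap_penalty)
      ex <- expectation_score(dup)
      if (!is.finite(ex) || ex > max_expectation) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirna_id, transcript_id = transcripts$id[ti],
        site_start = a - 1L, site_end = a - 1L + w,
        expectation = ex, mode = classify_inhibition(dup, central_range),
        flank_up_seq = if (a > 1)
          substr(tseq, max(1L, a - flank_up), a - 1L) else "",
        flank_down_seq = if (a + w <= n)
          substr(tseq, a + w, min(n, a + w - 1L + flank_down)) else "",
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    sites <- do.call(rbind, rows)
    # merge overlapping sites, keeping the lower expectation; at equal
    # expectation prefer the bulge-free window (width closest to the miRNA)
    sites <- sites[order(sites$expectation,
                         abs((sites$site_end - sites$site_start) -
                               length(mir)),
                         sites$site_start), , drop = FALSE]
    kept <- logical(0); ks <- integer(0); ke <- integer(0)
    keep_row <- logical(nrow(sites))
    for (k in seq_len(nrow(sites))) {
      ov <- any(sites$site_start[k] < ke & sites$site_end[k] > ks)
      if (!ov) {
        keep_row[k] <- TRUE
        ks <- c(ks, sites$site_start[k]); ke <- c(ke, sites$site_end[k])
      }
    }
    out[[length(out) + 1L]] <- sites[keep_row, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), mode = character(),
                      flank_up_seq = character(),
                      flank_down_seq = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$expectation, res$transcript_id, res$site_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, max_sites)
}

#' Scan a set of miRNAs against a transcriptome
#'
#' @param mirnas data.frame with columns `id`, `seq`.
#' @param transcripts data.frame with columns `id`, `seq`.
#' @param ... Passed to [scan_transcript()].
#' @return Row-bound [scan_transcript()] results.
#' @export
scan_transcriptome <- function(mirnas, transcripts, ...) {
  res <- lapply(seq_len(nrow(mirnas)), function(i) {
    scan_transcript(mirnas$id[i], mirnas$seq[i], transcripts, ...)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
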