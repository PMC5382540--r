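# miRNA:target coupling, key-gene ranking and term enrichment.
#
# Expression profiles are relative expression over the four treatments
# (control, NaCl, NaCl+TU, TU), control-normalised so the control entry is
# 1. Coupling is the Pearson correlation of miRNA and target profiles;
# canonical miRNA-mediated repression gives a negative r, decoupled pairs a
# positive one. Key genes are nominated by ranking targets on the
# NaCl+TU - TU expression difference and applying a 2-fold cut-off on the
# NaCl vs NaCl+TU contrast.

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient; `NA` with a warning if either vector
#'   has zero variance (indeterminate).
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation indeterminate")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Classify miRNA:target coupling from the correlation
#'
#' `inverse` (canonical repression) iff r <= `inverse_max`; `decoupled`
#' (deviation from miRNA-mediated repression) iff r >= `decoupled_min`;
#' otherwise, or for indeterminate r, `indeterminate`.
#'
#' @param r Pearson correlation (may be NA).
#' @param inverse_max,decoupled_min Class thresholds.
#' @return Character class.
#' @export
classify_coupling <- function(r, inverse_max = -0.25, decoupled_min = 0.25) {
  if (is.na(r)) return("indeterminate")
  if (r <= inverse_max) "inverse"
  else if (r >= decoupled_min) "decoupled"
  else "indeterminate"
}

#' Rank target genes and flag key genes
#'
#' For each target the NaCl+TU minus TU expression difference (`delta_tu`)
#' is computed and targets are ranked highest to lowest (ties broken by
#' id). A target is flagged a key gene iff the fold ratio between its
#' NaCl+TU and NaCl expression (larger over smaller) is at least
#' `fold_cutoff` and `delta_tu` is positive. Both the ranked delta and the
#' fold ratio are reported so either stage of the rule can be audited.
#'
#' @param profiles data.frame with columns `target_id`, `organ`, `control`,
#'   `nacl`, `nacl_tu`, `tu` (relative expression, fold over control).
#' @param fold_cutoff Fold cut-off on the NaCl vs NaCl+TU contrast.
#' @return data.frame per organ with `target_id`, `organ`, `delta_tu`,
#'   `fold_nacl_vs_nacltu`, `rank` (within organ), `key_gene`.
#' @export
rank_targets <- function(profiles, fold_cutoff = 2.0) {
  stopifnot(all(c("target_id", "nacl", "nacl_tu", "tu") %in%
                  colnames(profiles)))
  if (!"organ" %in% colnames(profiles)) profiles$organ <- "root"
  out <- lapply(split(profiles, profiles$organ), function(p) {
    delta <- p$nacl_tu - p$tu
    hi <- pmax(p$nacl_tu, p$nacl); lo <- pmin(p$nacl_tu, p$nacl)
    fold <- ifelse(lo > 0, hi / lo, Inf)
    ord <- order(-delta, p$target_id)
    data.frame(target_id = p$target_id[ord], organ = p$organ[ord],
               delta_tu = delta[ord], fold_nacl_vs_nacltu = fold[ord],
               rank = seq_along(ord),
               key_gene = (fold[ord] >= fold_cutoff) & (delta[ord] > 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Term enrichment by Fisher exact test with Bonferroni correction
#'
#' For every term annotated in the universe, a one-sided Fisher exact test
#' asks whether the term is over-represented among the selected ids; raw
#' p-values are Bonferroni-corrected by the number of tested terms.
#'
#' @param selected Character vector of selected ids (subset of `universe`).
#' @param universe Character vector of all ids.
#' @param term_map data.frame with columns `id`, `term`.
#' @param alpha Corrected-p threshold for the `enriched` flag.
#' @return data.frame per term: counts, `p`, `p_bonferroni`, `enriched`,
#'   sorted by corrected p.
#' @export
enrich_terms <- function(selected, universe, term_map, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  stopifnot(all(selected %in% universe))
  term_map <- term_map[term_map$id %in% universe, , drop = FALSE]
  terms <- sort(unique(term_map$term))
  n_sel <- length(selected); n_uni <- length(universe)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(term_map$id[term_map$term == tm])
    k <- sum(selected %in% with_term)
    K <- length(with_term)
    tab <- matrix(c(k, n_sel - k, K - k, (n_uni - n_sel) - (K - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, n_selected_with = k, n_selected = n_sel,
               n_universe_with = K, n_universe = n_uni, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * length(terms))
  out$enriched <- out$p_bonferroni < alpha
  out[order(out$p_bonferroni, out$term), , drop = FALSE]
}

#' Couple miRNAs to targets and nominate key genes, end to end
#'
#' Joins differentially expressed miRNAs to their scored target sites,
#' computes the Pearson coupling of each miRNA:target pair over the four
#' treatment profiles, classifies the coupling, ranks the targets and flags
#' key genes per organ. Targets without an expression profile are excluded
#' with a logged count.
#'
#' @param de_mirna_ids Ids of differentially expressed miRNAs.
#' @param target_sites data.frame from [scan_transcriptome()].
#' @param expression data.frame with columns `entity_id`, `organ`,
#'   `control`, `nacl`, `nacl_tu`, `tu`, holding profiles for both miRNAs
#'   and targets (relative expression, fold over control).
#' @param fold_cutoff Key-gene fold cut-off.
#' @param inverse_max,decoupled_min Coupling class thresholds.
#' @return data.frame per organ and target: coupling (`mirna_id`, `r`,
#'   `coupling`), ranking (`delta_tu`, `fold_nacl_vs_nacltu`, `rank`) and
#'   the `key_gene` flag. Attribute `n_missing_expression` counts excluded
#'   pairs.
#' @export
end_to_end_keygenes <- function(de_mirna_ids, target_sites, expression,
                                fold_cutoff = 2.0, inverse_max = -0.25,
                                decoupled_min = 0.25) {
  sites <- target_sites[target_sites$mirna_id %in% de_mirna_ids, ,
                        drop = FALSE]
  pairs <- unique(sites[, c("mirna_id", "transcript_id")])
  n_missing <- 0L
  out <- list()
  for (organ in unique(expression$organ)) {
    ex <- expression[expression$organ == organ, , drop = FALSE]
    prof <- function(id) {
      i <- match(id, ex$entity_id)
      if (is.na(i)) return(NULL)
      as.numeric(ex[i, c("control", "nacl", "nacl_tu", "tu")])
    }
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      mp <- prof(pairs$mirna_id[k]); tp <- prof(pairs$transcript_id[k])
      if (is.null(mp) || is.null(tp)) {
        n_missing <- n_missing + 1L
        next
      }
      r <- suppressWarnings(pearson_r(mp, tp))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = pairs$mirna_id[k], target_id = pairs$transcript_id[k],
        organ = organ, r = r, coupling = classify_coupling(r, inverse_max,
                                                           decoupled_min),
        control = tp[1], nacl = tp[2], nacl_tu = tp[3], tu = tp[4],
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    cp <- do.call(rbind, rows)
    rk <- rank_targets(cp[!duplicated(cp$target_id),
                          c("target_id", "organ", "control", "nacl",
                            "nacl_tu", "tu")], fold_cutoff)
    out[[length(out) + 1L]] <- merge(cp, rk[, c("target_id", "organ",
                                                "delta_tu",
                                                "fold_nacl_vs_nacltu",
                                                "rank", "key_gene")],
                                     by = c("target_id", "organ"))
  }
  if (n_missing) {
    message(n_missing, " miRNA:target pair(s) without expression excluded")
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  if (nrow(res)) res <- res[order(res$organ, res$rank), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_missing_expression") <- n_missing
  res
}
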