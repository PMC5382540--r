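# Count normalisation and differential-expression calling. The test is a
# two-sided Fisher exact test on pooled group counts (candidate counts vs
# the remainder of each group's library mass) - self-contained and exactly
# checkable against hypergeometric tails. It is anti-conservative under
# strong overdispersion, which the simulator's dispersion knob quantifies.

#' Counts-per-million normalisation
#'
#' @param counts Non-negative integer matrix (rows = candidates, columns =
#'   libraries). Column sums are the library sizes and must be positive.
#' @return Numeric matrix of CPM values.
#' @export
normalize_cpm <- function(counts) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("zero library size in count matrix")
  t(t(counts) / libsize) * 1e6
}

#' Differential-expression test between two treatment groups
#'
#' Per candidate, the log2 fold change is computed from group-mean CPM with
#' a pseudocount of 0.5, and the p-value from a two-sided Fisher exact test
#' on the 2x2 table of pooled group counts (candidate vs remaining counts,
#' treatment vs reference). Benjamini-Hochberg FDR is computed across rows
#' within the comparison.
#'
#' @param counts Count matrix (rows = candidates, named; columns = libraries).
#' @param treat_cols,ref_cols Column indices or names of the treatment and
#'   reference libraries (at least one each).
#' @param comparison Label stored in the result.
#' @return data.frame: `id`, `comparison`, `log2fc`, `p`, `fdr`.
#' @export
de_test <- function(counts, treat_cols, ref_cols, comparison = "treat_vs_ref") {
  counts <- as.matrix(counts)
  stopifnot(length(treat_cols) >= 1, length(ref_cols) >= 1)
  cpm <- normalize_cpm(counts)
  mean_t <- rowMeans(cpm[, treat_cols, drop = FALSE])
  mean_r <- rowMeans(cpm[, ref_cols, drop = FALSE])
  log2fc <- log2(mean_t + 0.5) - log2(mean_r + 0.5)
  sum_t <- rowSums(counts[, treat_cols, drop = FALSE])
  sum_r <- rowSums(counts[, ref_cols, drop = FALSE])
  tot_t <- sum(counts[, treat_cols])
  tot_r <- sum(counts[, ref_cols])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(sum_t[i], tot_t - sum_t[i],
                    sum_r[i], tot_r - sum_r[i]), 2, 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  p <- pmin(p, 1)
  data.frame(id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             comparison = comparison, log2fc = log2fc, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differential expression
#'
#' A candidate is called `up` iff log2FC >= `min_abs_log2fc` and
#' p < `alpha`; `down` iff log2FC <= -`min_abs_log2fc` and p < `alpha`;
#' otherwise `ns`. The fold-change threshold is inclusive, the p threshold
#' strict. Calls use the raw p-value; the FDR is reported alongside.
#'
#' @param results data.frame from [de_test()].
#' @param min_abs_log2fc Minimum |log2FC| (inclusive).
#' @param alpha p-value threshold (strict).
#' @return `results` with an added `call` column.
#' @export
call_de <- function(results, min_abs_log2fc = 1, alpha = 0.05) {
  call <- rep("ns", nrow(results))
  sig <- results$p < alpha
  call[sig & results$log2fc >= min_abs_log2fc] <- "up"
  call[sig & results$log2fc <= -min_abs_log2fc] <- "down"
  results$call <- call
  results
}

#' Partition DE candidates into Venn regions across three treatments
#'
#' @param calls Named list of called [de_test()] results (one per
#'   treatment-vs-control comparison, e.g. NaCl, NaCl+TU, TU). A candidate
#'   belongs to a treatment's set iff its call is not `ns`.
#' @return data.frame: `id`, `region` (comma-joined treatment labels) for
#'   every candidate DE in at least one treatment; attribute `region_sizes`
#'   is a named count vector over all 7 regions.
#' @export
treatment_specific_sets <- function(calls) {
  stopifnot(length(calls) == 3, !is.null(names(calls)))
  labs <- names(calls)
  ids <- unique(unlist(lapply(calls, function(d) d$id)))
  inset <- sapply(calls, function(d) ids %in% d$id[d$call != "ns"])
  if (length(ids) == 1) inset <- matrix(inset, nrow = 1)
  region <- apply(inset, 1, function(z) paste(labs[z], collapse = ","))
  keep <- nzchar(region)
  out <- data.frame(id = ids[keep], region = region[keep],
                    stringsAsFactors = FALSE)
  all_regions <- unlist(lapply(1:3, function(k) {
    apply(utils::combn(labs, k), 2, paste, collapse = ",")
  }))
  sizes <- stats::setNames(integer(length(all_regions)), all_regions)
  tb <- table(out$region)
  sizes[names(tb)] <- as.integer(tb)
  attr(out, "region_sizes") <- sizes
  out
}
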