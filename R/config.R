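#' Pipeline configuration
#'
#' Collects every numeric threshold used along the analysis chain into a
#' single validated object. Defaults reproduce the study design this
#' pipeline models: 3' adapter trimming requires a minimum 8 nt adapter
#' alignment, reads are size-selected to 18--30 nt, mature miRNAs to
#' 20--24 nt, the clustering window extends the founding read by 3 nt
#' upstream and 5 nt downstream (in strand orientation, so isomiRs join the
#' founder's cluster), paired arm clusters must be less than 150 nt apart,
#' differential expression requires |log2 fold change| >= 1 at p < 0.05,
#' target sites are kept up to expectation 2.0 with complementarity scored
#' over at most 20 positions, a central mismatch in miRNA positions 9--11
#' signals translational inhibition, accessibility flanks of 17 nt upstream
#' and 13 nt downstream are attached to each site, and key genes must pass
#' a 2-fold cut-off.
#'
#' @param adapter 3' adapter sequence appended by library preparation.
#' @param min_adapter_overlap Minimum length of the adapter prefix that must
#'   align at the trim point (nt).
#' @param read_len_min,read_len_max Size-selection bounds for kept reads (nt).
#' @param mirna_len_min,mirna_len_max Accepted mature miRNA lengths (nt),
#'   inclusive.
#' @param cluster_upstream_flank,cluster_downstream_flank Window flanks added
#'   before the cluster start and after the cluster end, in strand
#'   orientation (nt).
#' @param max_pair_gap Arm clusters pair only if their gap is strictly less
#'   than this distance (nt).
#' @param fold_min_loop Minimum hairpin-loop size used when folding
#'   candidate precursors for the structural screen. Plant pre-miRNA
#'   terminal loops are rarely smaller than ~10 nt; a larger minimum stops
#'   the base-pair-maximising fold from fragmenting genuine stems into
#'   spurious micro-hairpins.
#' @param de_min_abs_log2fc Minimum |log2 fold change| for a DE call.
#' @param de_alpha p-value threshold for a DE call (strict).
#' @param target_max_expectation Maximum expectation score of an emitted
#'   target site.
#' @param hspsize Number of miRNA 5' positions scored for complementarity.
#' @param central_mismatch_range Inclusive miRNA position range whose
#'   mismatches imply translational inhibition.
#' @param flank_up,flank_down Lengths of the transcript flanks reported
#'   around each target site (nt).
#' @param max_targets_per_mirna Cap on reported sites per miRNA across the
#'   transcriptome.
#' @param keygene_fold_cutoff Fold cut-off used by the key-gene rule.
#' @param enrichment_alpha Bonferroni-corrected p threshold for term
#'   enrichment.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @return A validated list of class `saltmir_config`.
#' @examples
#' cfg <- pipeline_config(adapter = "CGCCTTGGCCGTACAGCAG")
#' cfg$max_pair_gap
#' @export
pipeline_config <- function(adapter = "CGCCTTGGCCGTACAGCAG",
                            min_adapter_overlap = 8L,
                            read_len_min = 18L, read_len_max = 30L,
                            mirna_len_min = 20L, mirna_len_max = 24L,
                            cluster_upstream_flank = 3L,
                            cluster_downstream_flank = 5L,
                            max_pair_gap = 150L,
                            fold_min_loop = 10L,
                            de_min_abs_log2fc = 1.0, de_alpha = 0.05,
                            target_max_expectation = 2.0, hspsize = 20L,
                            central_mismatch_range = c(9L, 11L),
                            flank_up = 17L, flank_down = 13L,
                            max_targets_per_mirna = 200L,
                            keygene_fold_cutoff = 2.0,
                            enrichment_alpha = 0.05,
                            rng_seed = 1L) {
  cfg <- list(adapter = dna_norm(adapter),
              min_adapter_overlap = as.integer(min_adapter_overlap),
              read_len_min = as.integer(read_len_min),
              read_len_max = as.integer(read_len_max),
              mirna_len_min = as.integer(mirna_len_min),
              mirna_len_max = as.integer(mirna_len_max),
              cluster_upstream_flank = as.integer(cluster_upstream_flank),
              cluster_downstream_flank = as.integer(cluster_downstream_flank),
              max_pair_gap = as.integer(max_pair_gap),
              fold_min_loop = as.integer(fold_min_loop),
              de_min_abs_log2fc = de_min_abs_log2fc, de_alpha = de_alpha,
              target_max_expectation = target_max_expectation,
              hspsize = as.integer(hspsize),
              central_mismatch_range = as.integer(central_mismatch_range),
              flank_up = as.integer(flank_up),
              flank_down = as.integer(flank_down),
              max_targets_per_mirna = as.integer(max_targets_per_mirna),
              keygene_fold_cutoff = keygene_fold_cutoff,
              enrichment_alpha = enrichment_alpha,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "saltmir_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    nchar(cfg$adapter) >= 1,
    cfg$min_adapter_overlap >= 1,
    cfg$read_len_min >= 1, cfg$read_len_min <= cfg$read_len_max,
    cfg$mirna_len_min >= 1, cfg$mirna_len_min <= cfg$mirna_len_max,
    cfg$cluster_upstream_flank >= 0, cfg$cluster_downstream_flank >= 0,
    cfg$max_pair_gap >= 0, cfg$fold_min_loop >= 1,
    cfg$de_alpha > 0, cfg$de_alpha < 1,
    cfg$enrichment_alpha > 0, cfg$enrichment_alpha < 1,
    cfg$target_max_expectation >= 0,
    cfg$hspsize >= 1,
    length(cfg$central_mismatch_range) == 2,
    cfg$central_mismatch_range[1] <= cfg$central_mismatch_range[2],
    cfg$flank_up >= 0, cfg$flank_down >= 0,
    cfg$max_targets_per_mirna >= 1,
    cfg$keygene_fold_cutoff > 0
  )
  invisible(cfg)
}

#' @export
print.saltmir_config <- function(x, ...) {
  cat("saltmir pipeline configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-26s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}
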