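# Pipeline driver: chains preprocess -> map -> cluster -> fold screen ->
# quantify -> DE -> target scan -> coupling/ranking, writing every
# intermediate table to the output directory. All outputs are plain TSV /
# GFF3 / FASTA with fixed formatting, so two runs under the same seed are
# byte-identical.

#' Run the full small-RNA analysis pipeline
#'
#' @param config `saltmir_config` from [pipeline_config()].
#' @param inputs Named list:
#'   * `fastq_manifest`: data.frame (or TSV path) with columns `library`,
#'     `treatment`, `replicate`, `path` - one FASTQ per library; requires
#'     `genome`.
#'   * `sam_manifest`: same columns, one SAM per library - alternative
#'     entry point; preprocess and map stages are skipped (noted in the
#'     report).
#'   * `genome`: FASTA path or data.frame (`id`, `seq`). Required with
#'     FASTQ input; with SAM input it is optional and enables the fold
#'     screen.
#'   * `contaminants` (optional): contaminant ncRNA FASTA path/table.
#'   * `transcripts` (optional): transcript FASTA path/table for target
#'     scanning.
#'   * `expression` (optional): expression TSV path/table with columns
#'     `entity_id`, `organ`, `control`, `nacl`, `nacl_tu`, `tu` (and
#'     optionally `type`) holding measured target-gene profiles.
#'   * `structures` (optional): data.frame/TSV (`candidate_id`,
#'     `structure`) of externally folded precursors, used instead of the
#'     internal fold.
#' @param out_dir Output directory (created).
#' @return Invisibly, the run report: a list of stage tallies, file paths
#'   and notes. Any stage failure aborts with the stage name.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  validate_config(config)
  set.seed(config$rng_seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(notes = character(0))
  as_table <- function(x) if (is.character(x)) read_tsv(x) else x
  as_fasta <- function(x) if (is.character(x)) read_fasta(x) else x

  have_fastq <- !is.null(inputs$fastq_manifest)
  have_sam <- !is.null(inputs$sam_manifest)
  if (!have_fastq && !have_sam) {
    saltmir_stop("config", "either fastq_manifest or sam_manifest required")
  }
  if (have_fastq && is.null(inputs$genome)) {
    saltmir_stop("config", "genome FASTA required with FASTQ input")
  }
  genome <- if (!is.null(inputs$genome)) as_fasta(inputs$genome) else NULL
  manifest <- as_table(if (have_fastq) inputs$fastq_manifest
                       else inputs$sam_manifest)
  needed <- c("library", "treatment", "replicate", "path")
  if (!all(needed %in% colnames(manifest))) {
    saltmir_stop("config", "manifest needs columns: ",
                 paste(needed, collapse = ", "))
  }
  lib_names <- manifest$library

  if (have_fastq) {
    ## -- preprocess: trim, size filter, contaminant filter ---------------
    contams <- if (!is.null(inputs$contaminants))
      as_fasta(inputs$contaminants) else NULL
    all_seqs <- character(0); all_lib <- integer(0)
    pre_tally <- list()
    for (li in seq_len(nrow(manifest))) {
      reads <- tryCatch(read_fastq(manifest$path[li]),
                        error = function(e) saltmir_stop("preprocess",
                                                         conditionMessage(e)))
      tr <- trim_adapter(reads$seq, config$adapter,
                         config$min_adapter_overlap)
      fl <- filter_reads(tr$seq, config$read_len_min, config$read_len_max,
                         contams)
      pre_tally[[li]] <- data.frame(
        library = lib_names[li], input = length(reads$seq),
        dropped_N = attr(reads, "n_dropped_N"),
        trimmed = sum(tr$trimmed), untrimmed_kept = sum(!tr$trimmed),
        dropped_length = unname(fl$tally["dropped_length"]),
        dropped_contaminant = unname(fl$tally["dropped_contaminant"]),
        kept = unname(fl$tally["kept"]), stringsAsFactors = FALSE)
      all_seqs <- c(all_seqs, fl$kept)
      all_lib <- c(all_lib, rep(li, length(fl$kept)))
    }
    report$preprocess <- do.call(rbind, pre_tally)
    write_tsv(report$preprocess, file.path(out_dir, "preprocess_tally.tsv"))

    ## -- collapse and map -------------------------------------------------
    unique_reads <- collapse_unique(all_seqs, all_lib, lib_names)
    write_tsv(unique_reads, file.path(out_dir, "collapsed_reads.tsv"))
    alignments <- tryCatch(map_exact(unique_reads, genome),
                           error = function(e) saltmir_stop("map",
                                                            conditionMessage(e)))
    report$map <- c(unique_reads = nrow(unique_reads),
                    placed = nrow(alignments),
                    unplaced_reads = attr(alignments, "n_unplaced"))
  } else {
    ## -- SAM entry point ---------------------------------------------------
    report$notes <- c(report$notes,
                      "SAM input: preprocess and map stages skipped")
    occ_seq <- character(0); occ_lib <- integer(0)
    aln_rows <- list()
    for (li in seq_len(nrow(manifest))) {
      sam <- tryCatch(read_sam_min(manifest$path[li]),
                      error = function(e) saltmir_stop("sam_import",
                                                       conditionMessage(e)))
      occ_seq <- c(occ_seq, sam$seq)
      occ_lib <- c(occ_lib, rep(li, nrow(sam)))
      aln_rows[[li]] <- sam
    }
    unique_reads <- collapse_unique(occ_seq, occ_lib, lib_names)
    write_tsv(unique_reads, file.path(out_dir, "collapsed_reads.tsv"))
    occ <- do.call(rbind, aln_rows)
    alignments <- unique(occ[, c("seq", "chrom", "start", "end", "strand")])
    alignments$total <- unique_reads$total[match(alignments$seq,
                                                 unique_reads$seq)]
    pl <- table(alignments$seq)
    alignments$n_placements <- as.integer(pl[alignments$seq])
    alignments <- alignments[, c("seq", "total", "chrom", "start", "end",
                                 "strand", "n_placements")]
    report$map <- c(unique_reads = nrow(unique_reads),
                    placed = nrow(alignments))
  }
  write_tsv(alignments, file.path(out_dir, "alignments.tsv"))

  ## -- cluster and pair ----------------------------------------------------
  clustering <- cluster_reads(alignments, config$cluster_upstream_flank,
                              config$cluster_downstream_flank)
  write_tsv(clustering$clusters, file.path(out_dir, "clusters.tsv"))
  candidates <- pair_clusters(clustering$clusters, config$max_pair_gap)
  report$cluster <- c(clusters = nrow(clustering$clusters),
                      paired_candidates = nrow(candidates),
                      overlapping_pairs = attr(candidates,
                                               "n_overlapping_pairs"))
  candidates <- filter_candidate_length(candidates, config$mirna_len_min,
                                        config$mirna_len_max)
  report$cluster["dropped_mature_length"] <-
    attr(candidates, "n_dropped_length")

  ## -- fold screen ----------------------------------------------------------
  ext_struct <- if (!is.null(inputs$structures))
    as_table(inputs$structures) else NULL
  if (!is.null(genome) || !is.null(ext_struct)) {
    fold_rows <- list()
    pass <- logical(nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
      cd <- candidates[i, ]
      pseq <- if (!is.null(genome)) precursor_seq(cd, genome) else NULL
      fold <- if (!is.null(ext_struct) &&
                    cd$candidate_id %in% ext_struct$candidate_id) {
        parse_dotbracket(pseq %||% strrep("N", nchar(
          ext_struct$structure[match(cd$candidate_id,
                                     ext_struct$candidate_id)])),
          ext_struct$structure[match(cd$candidate_id,
                                     ext_struct$candidate_id)])
      } else {
        fold_maxpair(pseq, min_loop = config$fold_min_loop)
      }
      hc <- hairpin_check(fold, mature_range_in_precursor(cd))
      pass[i] <- hc$pass
      fold_rows[[i]] <- data.frame(
        candidate_id = cd$candidate_id, structure = fold$structure,
        n_pairs = fold$n_pairs, paired_frac = round(hc$paired_frac, 4),
        n_loops = hc$n_loops, pass = hc$pass, stringsAsFactors = FALSE)
    }
    fold_metrics <- if (length(fold_rows)) do.call(rbind, fold_rows) else
      data.frame(candidate_id = character(), structure = character(),
                 n_pairs = integer(), paired_frac = numeric(),
                 n_loops = integer(), pass = logical())
    write_tsv(fold_metrics, file.path(out_dir, "fold_metrics.tsv"))
    report$fold <- c(tested = nrow(candidates), passed = sum(pass))
    candidates <- candidates[pass, , drop = FALSE]
  } else {
    report$notes <- c(report$notes,
                      "no genome or external structures: fold screen skipped")
  }
  write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
  write_candidates_gff3(candidates, file.path(out_dir, "candidates.gff3"))

  ## -- quantify and DE -------------------------------------------------------
  q <- quantify(candidates, clustering, unique_reads)
  counts <- q$counts
  write_tsv(data.frame(candidate_id = rownames(counts), counts,
                       check.names = FALSE),
            file.path(out_dir, "counts.tsv"))
  treatments <- unique(manifest$treatment)
  ref <- treatments[1]
  de_calls <- list()
  if (nrow(counts) > 0) {
    for (tr in setdiff(treatments, ref)) {
      res <- de_test(counts, which(manifest$treatment == tr),
                     which(manifest$treatment == ref),
                     comparison = paste0(tr, "_vs_", ref))
      res <- call_de(res, config$de_min_abs_log2fc, config$de_alpha)
      de_calls[[tr]] <- res
      write_tsv(res, file.path(out_dir, paste0("de_", tr, ".tsv")))
    }
    if (length(de_calls) == 3) {
      venn <- treatment_specific_sets(de_calls)
      sizes <- attr(venn, "region_sizes")
      write_tsv(data.frame(region = names(sizes), n = as.integer(sizes)),
                file.path(out_dir, "venn_regions.tsv"))
      report$venn <- sizes
    }
    report$de <- vapply(de_calls, function(d) sum(d$call != "ns"),
                        integer(1))
  }

  ## -- target scan ------------------------------------------------------------
  sites <- NULL
  if (!is.null(inputs$transcripts) && nrow(candidates) > 0) {
    transcripts <- as_fasta(inputs$transcripts)
    mirnas <- data.frame(id = candidates$candidate_id,
                         seq = candidates$mature_seq,
                         stringsAsFactors = FALSE)
    sites <- scan_transcriptome(
      mirnas, transcripts,
      max_expectation = config$target_max_expectation,
      hspsize = config$hspsize, central_range = config$central_mismatch_range,
      flank_up = config$flank_up, flank_down = config$flank_down,
      max_sites = config$max_targets_per_mirna)
    write_tsv(sites, file.path(out_dir, "target_sites.tsv"))
    report$targets <- c(mirnas_scanned = nrow(mirnas),
                        sites_found = nrow(sites))
  }

  ## -- coupling and key genes --------------------------------------------------
  if (!is.null(sites) && nrow(sites) > 0 && !is.null(inputs$expression)) {
    expr_in <- as_table(inputs$expression)
    if ("type" %in% colnames(expr_in)) {
      expr_in <- expr_in[expr_in$type == "target", , drop = FALSE]
    }
    organ <- unique(expr_in$organ)[1] %||% "root"
    # miRNA profiles derived from the pipeline's own quantification:
    # treatment-mean CPM as fold over control
    cpm <- normalize_cpm(counts)
    mir_prof <- t(apply(cpm, 1, function(v) {
      m <- tapply(v, manifest$treatment, mean)[treatments]
      m / max(m[ref], .Machine$double.eps)
    }))
    mir_expr <- data.frame(entity_id = rownames(counts), organ = organ,
                           control = mir_prof[, 1], nacl = mir_prof[, 2],
                           nacl_tu = mir_prof[, 3], tu = mir_prof[, 4],
                           stringsAsFactors = FALSE)
    expression <- rbind(mir_expr,
                        expr_in[, c("entity_id", "organ", "control", "nacl",
                                    "nacl_tu", "tu")])
    de_ids <- unique(unlist(lapply(de_calls, function(d)
      d$id[d$call != "ns"])))
    keygenes <- end_to_end_keygenes(de_ids, sites, expression,
                                    config$keygene_fold_cutoff)
    write_tsv(keygenes, file.path(out_dir, "keygenes.tsv"))
    report$keygenes <- c(
      pairs = nrow(keygenes),
      key_genes = if (nrow(keygenes)) sum(keygenes$key_gene) else 0L,
      missing_expression = attr(keygenes, "n_missing_expression"))
  }

  ## -- run report -----------------------------------------------------------
  rep_lines <- unlist(lapply(names(report), function(nm) {
    x <- report[[nm]]
    if (is.data.frame(x)) {
      paste0(nm, ".", x$library, ".kept\t", x$kept)
    } else if (is.character(x)) {
      if (length(x)) paste0("note\t", x) else character(0)
    } else {
      paste0(nm, ".", names(x), "\t", unname(x))
    }
  }))
  writeLines(rep_lines, file.path(out_dir, "report.tsv"))
  invisible(report)
}
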