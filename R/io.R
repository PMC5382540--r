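# File-format frontier. Inside the package every interval is 0-based
# half-open; conversions to the 1-based inclusive conventions of SAM and
# GFF3 happen only in this file.

#' Read a FASTA file
#'
#' A strict FASTA reader with diagnostic parse errors: malformed headers and
#' empty sequences are reported with the offending line number. Sequences
#' are upper-cased; U is accepted and preserved (T and U are treated as the
#' same base downstream). Duplicate record ids are kept, with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `seq`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  is_hdr <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (!any(is_hdr)) {
    if (!any(nonblank)) return(data.frame(id = character(), seq = character()))
    stop("FASTA parse error at line 1: no '>' header found")
  }
  first_hdr <- which(is_hdr)[1]
  stray <- which(nonblank & !is_hdr)
  if (length(stray) && stray[1] < first_hdr) {
    stop("FASTA parse error at line ", stray[1], ": sequence before header")
  }
  ids <- character(0); seqs <- character(0); hdr_line <- integer(0)
  cur <- NULL; buf <- character(0)
  flush_rec <- function() {
    if (is.null(cur)) return()
    s <- toupper(paste(buf, collapse = ""))
    if (!nzchar(s)) {
      stop("FASTA parse error at line ", hdr_line[length(hdr_line)],
           ": empty sequence for record '", cur, "'")
    }
    ids[length(ids) + 1L] <<- cur
    seqs[length(seqs) + 1L] <<- s
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush_rec()
      id <- strsplit(trimws(sub("^>", "", ln)), "[ \t]")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", i, ": empty header")
      }
      cur <- id; buf <- character(0); hdr_line <- c(hdr_line, i)
    } else if (nzchar(trimws(ln))) {
      s <- gsub("[ \t]", "", ln)
      if (grepl("[^ACGTUNacgtun]", s)) {
        stop("FASTA parse error at line ", i, ": invalid character in sequence")
      }
      buf <- c(buf, s)
    }
  }
  flush_rec()
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids kept: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param records data.frame with columns `id`, `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", records$id[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Expects 4-line records. Qualities are retained in the returned table but
#' the downstream pipeline discards them when collapsing reads. Reads
#' containing N are dropped at parse time (N breaks complementarity
#' scoring); the dropped count is attached as attribute `n_dropped_N` and
#' logged.
#'
#' @param path Path to a FASTQ file.
#' @param drop_n Drop reads containing N (default TRUE).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path, drop_n = TRUE) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) {
    out <- data.frame(id = character(), seq = character(), qual = character())
    attr(out, "n_dropped_N") <- 0L
    return(out)
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error: ", path, " has ", length(lines),
         " lines, not a multiple of 4")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]; seq <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]; qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 1L,
         ": malformed record")
  }
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism)) {
    stop("FASTQ parse error: sequence/quality length mismatch in record ",
         mism[1], " ('", sub("^@", "", hdr[mism[1]]), "')")
  }
  id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[`, character(1), 1L))
  keep <- rep(TRUE, length(seq))
  n_dropped <- 0L
  if (drop_n) {
    keep <- !grepl("N", seq, fixed = TRUE)
    n_dropped <- sum(!keep)
    if (n_dropped) message(n_dropped, " read(s) containing N dropped from ", path)
  }
  out <- data.frame(id = id[keep], seq = seq[keep], qual = qual[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_N") <- n_dropped
  out
}

#' Write reads as FASTQ
#' @param records data.frame with `id`, `seq` and optionally `qual` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual %||% NULL
  if (is.null(qual)) qual <- strrep("I", nchar(records$seq))
  out <- as.vector(rbind(paste0("@", records$id), records$seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Consumes primary/secondary ungapped alignments (CIGAR `<n>M`) from a
#' headered SAM file and converts them to the package's internal 0-based
#' half-open coordinates. FLAG bit 0x10 maps to the minus strand and the
#' stored read sequence is reverse-complemented back to the as-sequenced
#' orientation so records agree with [map_exact()] output. Unmapped and
#' gapped records are skipped with logged tallies.
#'
#' @param path Path to a SAM file with an `@SQ` header for every reference
#'   used by a mapped record.
#' @return data.frame with columns `seq`, `chrom`, `start`, `end`, `strand`;
#'   attributes `n_unmapped` and `n_gapped` hold skip tallies.
#' @export
read_sam_min <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- sub("^SN:", "", unlist(lapply(strsplit(sq, "\t"), function(f) {
    f[startsWith(f, "SN:")]
  })))
  empty <- data.frame(seq = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character())
  if (!length(body)) {
    attr(empty, "n_unmapped") <- 0L; attr(empty, "n_gapped") <- 0L
    return(empty)
  }
  f <- strsplit(body, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_unmapped <- sum(unmapped)
  if (n_unmapped) message(n_unmapped, " unmapped SAM record(s) skipped")
  f <- f[!unmapped]; flag <- flag[!unmapped]
  if (!length(f)) {
    attr(empty, "n_unmapped") <- n_unmapped; attr(empty, "n_gapped") <- 0L
    return(empty)
  }
  rname <- vapply(f, `[`, character(1), 3L)
  miss <- setdiff(unique(rname), refs)
  if (length(miss)) {
    stop("SAM reference(s) missing from @SQ header: ",
         paste(miss, collapse = ", "))
  }
  cigar <- vapply(f, `[`, character(1), 6L)
  gapped <- !grepl("^[0-9]+M$", cigar)
  n_gapped <- sum(gapped)
  if (n_gapped) message(n_gapped, " gapped/clipped SAM record(s) skipped")
  f <- f[!gapped]; flag <- flag[!gapped]; rname <- rname[!gapped]
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  seq <- toupper(vapply(f, `[`, character(1), 10L))
  minus <- bitwAnd(flag, 16L) != 0L
  out <- data.frame(
    seq = ifelse(minus, revcomp(seq), seq),
    chrom = rname,
    start = pos - 1L,
    end = pos - 1L + nchar(seq),
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_gapped") <- n_gapped
  out
}

#' Write hairpin candidates as GFF3
#'
#' One `miRNA_primary_transcript` feature per candidate precursor with two
#' child `miRNA` features for the mature and star arms. Internal 0-based
#' half-open coordinates are converted to GFF3 1-based inclusive columns.
#'
#' @param candidates Candidate table from [pair_clusters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(candidates) || nrow(candidates) == 0) return(invisible(path))
  gff_line <- function(chrom, type, start0, end0, strand, attrs) {
    paste(chrom, "saltmir", type, start0 + 1L, end0, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    pid <- cd$candidate_id
    writeLines(c(
      gff_line(cd$chrom, "miRNA_primary_transcript",
               cd$precursor_start, cd$precursor_end, cd$strand,
               sprintf("ID=%s;Name=%s", pid, pid)),
      gff_line(cd$chrom, "miRNA", cd$mature_start, cd$mature_end, cd$strand,
               sprintf("ID=%s_mature;Parent=%s;arm=mature;seq=%s",
                       pid, pid, cd$mature_seq)),
      gff_line(cd$chrom, "miRNA", cd$star_start, cd$star_end, cd$strand,
               sprintf("ID=%s_star;Parent=%s;arm=star;seq=%s",
                       pid, pid, cd$star_seq))
    ), con)
  }
  invisible(path)
}

# TSV helpers: fixed settings so repeated runs are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
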