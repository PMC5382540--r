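# Synthetic ground truth: genomes with planted pre-miRNA hairpins,
# treatment-structured small-RNA libraries, and target transcripts whose
# expression is inversely coupled to (or deliberately decoupled from) their
# miRNA. The generator defines the conditions every downstream stage is
# tested against: mature lengths with a 23 > 21 > 22 nt mode inside 20-24
# nt, size-selected reads of 18-30 nt after trimming, two read clusters per
# hairpin (star arm at 10% of mature abundance), negative-binomial counts
# over the four treatments (control, NaCl, NaCl+TU, TU) with two
# replicates, and isomiR jitter bounded by the clustering window.

TREATMENTS <- c("control", "nacl", "nacl_tu", "tu")

# Mature-length distribution: mode at 23 nt, then 21, then 22.
MATURE_LEN_PROBS <- c(`20` = 0.06, `21` = 0.24, `22` = 0.16, `23` = 0.44,
                      `24` = 0.10)

#' Generate a genome with planted pre-miRNA hairpins
#'
#' The background is i.i.d. uniform nucleotides; each hairpin (5' arm +
#' loop + 3' arm, the star arm a perfect or G:U-substituted reverse
#' complement of the mature arm) is inserted at a recorded position, on the
#' minus strand with probability 0.5, with at least `min_spacing` nt
#' between hairpins so clusters of different hairpins can never pair.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (nt).
#' @param n_hairpins Number of planted hairpins.
#' @param loop_len Loop length (nt, >= 3).
#' @param gu_subs Number of G:U wobbles planted in each star arm. At least
#'   one is needed for the two arms to be distinguishable sequences (a
#'   perfect-revcomp stem maps each arm read onto both arms).
#' @param min_spacing Minimum distance between hairpins (nt).
#' @param seed Integer RNG seed.
#' @return list with `genome` (data.frame `id`, `seq`) and `truth`
#'   (data.frame per hairpin: `mirna_id`, `chrom`, `start`, `end`,
#'   `strand`, `arm` (5p/3p = side carrying the mature miRNA),
#'   `mature_seq`, `star_seq`, `loop_seq`, and 0-based half-open genomic
#'   intervals `mature_start`, `mature_end`, `star_start`, `star_end`).
#' @export
make_genome <- function(n_chrom = 2L, chrom_len = 20000L, n_hairpins = 20L,
                        loop_len = 15L, gu_subs = 2L, min_spacing = 300L,
                        seed = 1L) {
  stopifnot(loop_len >= 3, n_chrom >= 1, chrom_len >= 1)
  set.seed(seed)
  chrom_ids <- sprintf("chr%d", seq_len(n_chrom))
  seqs <- vapply(chrom_ids, function(.) random_seq(chrom_len), character(1))
  truth <- NULL
  if (n_hairpins > 0) {
    per_chrom <- diff(floor(seq(0, n_hairpins, length.out = n_chrom + 1L)))
    edge <- 200L
    rows <- list()
    hp_i <- 0L
    for (ci in seq_len(n_chrom)) {
      k <- per_chrom[ci]
      if (k == 0) next
      slot <- (chrom_len - 2L * edge) %/% k
      max_hp <- 2L * 24L + loop_len
      if (slot < max_hp + min_spacing) {
        stop("infeasible packing: ", k, " hairpins do not fit on a ",
             chrom_len, " nt chromosome with ", min_spacing, " nt spacing")
      }
      for (j in seq_len(k)) {
        hp_i <- hp_i + 1L
        lm <- as.integer(sample(names(MATURE_LEN_PROBS), 1,
                                prob = MATURE_LEN_PROBS))
        repeat {
          mature <- random_seq(lm)
          star <- revcomp(mature)
          # wobble-eligible star positions: C faces a mature G (C->T gives
          # G:U), A faces a mature T (A->G gives U:G)
          elig <- which(seq_chars(star) %in% c("A", "C"))
          if (length(elig) >= gu_subs) break
        }
        for (p in utils::head(sample(elig), gu_subs)) {
          b <- substr(star, p, p)
          substr(star, p, p) <- if (b == "C") "T" else "G"
        }
        # loops are drawn from a non-self-pairing alphabet so the planted
        # terminal loop is genuinely unstructured
        loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                      collapse = "")
        arm <- sample(c("5p", "3p"), 1)
        hairpin <- if (arm == "5p") paste0(mature, loop, star)
          else paste0(star, loop, mature)
        hl <- nchar(hairpin)
        jitter <- sample.int(slot - max_hp - min_spacing + 1L, 1) - 1L
        start <- edge + (j - 1L) * slot + jitter  # 0-based
        strand <- sample(c("+", "-"), 1)
        fwd <- if (strand == "+") hairpin else revcomp(hairpin)
        substr(seqs[ci], start + 1L, start + hl) <- fwd
        # genomic intervals of the arms (0-based half-open, forward)
        l1 <- if (arm == "5p") lm else nchar(star)
        if (strand == "+") {
          a1 <- c(start, start + l1)
          a2 <- c(start + l1 + loop_len, start + hl)
        } else {
          # hairpin 5' end sits at the forward right edge
          a1 <- c(start + hl - l1, start + hl)
          a2 <- c(start, start + hl - l1 - loop_len)
        }
        if (arm == "5p") { mi <- a1; si <- a2 } else { mi <- a2; si <- a1 }
        rows[[hp_i]] <- data.frame(
          mirna_id = sprintf("mir%02d", hp_i), chrom = chrom_ids[ci],
          start = start, end = start + hl, strand = strand, arm = arm,
          mature_seq = mature, star_seq = star, loop_seq = loop,
          mature_start = mi[1], mature_end = mi[2],
          star_start = si[1], star_end = si[2], stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
  } else {
    truth <- data.frame(mirna_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), arm = character(),
                        mature_seq = character(), star_seq = character(),
                        loop_seq = character(), mature_start = integer(),
                        mature_end = integer(), star_start = integer(),
                        star_end = integer())
  }
  list(genome = data.frame(id = chrom_ids, seq = unname(seqs),
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Default treatment profile for planted hairpins
#'
#' Assigns each hairpin an expression pattern over the four treatments
#' (multipliers of `base_depth`): hairpin 1 is `redox_rescued` (induced by
#' NaCl, suppressed when thiourea is co-applied, induced by TU alone) - the
#' pattern whose inversely coupled target carries the key-gene signature;
#' the rest cycle through `salt_up` (4x in NaCl and NaCl+TU, a planted
#' log2FC of +2), `salt_down` (0.25x, log2FC -2) and `flat`.
#'
#' @param truth Truth table from [make_genome()].
#' @param replicates Biological replicates per treatment (>= 2).
#' @param base_depth Mean mature-arm read count per library at multiplier 1.
#' @param dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @return list of class `saltmir_profile`: `treatments`, `replicates`,
#'   `dispersion`, `means` (hairpins x treatments), `pattern` (per hairpin).
#' @export
default_profile <- function(truth, replicates = 2L, base_depth = 1000,
                            dispersion = 0.05) {
  stopifnot(replicates >= 2, base_depth > 0, dispersion >= 0)
  pat_mult <- list(
    redox_rescued = c(1, 2, 0.2, 1.8),
    salt_up = c(1, 4, 4, 1),
    salt_down = c(1, 0.25, 0.25, 1),
    flat = c(1, 1, 1, 1))
  n <- nrow(truth)
  pattern <- character(n)
  if (n >= 1) pattern[1] <- "redox_rescued"
  if (n >= 2) {
    # composition-balanced design: the extra read mass of up-regulated
    # hairpins (+3x each) cancels against down-regulated ones (-0.75x each,
    # four per up), so library totals stay comparable across treatments and
    # CPM fold changes are not compressed by compositional bias
    k_up <- max(1L, round((n - 1L) / 6))
    k_down <- min(n - 1L - k_up, 4L * k_up)
    pattern[2:n] <- rep(c(rep("salt_up", k_up), rep("salt_down", k_down),
                          rep("flat", n - 1L - k_up - k_down)),
                        length.out = n - 1L)
  }
  means <- t(vapply(pattern, function(p) base_depth * pat_mult[[p]],
                    numeric(4)))
  dimnames(means) <- list(truth$mirna_id, TREATMENTS)
  structure(list(treatments = TREATMENTS, replicates = as.integer(replicates),
                 dispersion = dispersion, means = means, pattern = pattern),
            class = "saltmir_profile")
}

# NB draw that degrades to Poisson at dispersion 0.
rcount <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate per-library small-RNA FASTQ files
#'
#' For every planted arm and library, a negative-binomial read count is
#' drawn around the treatment mean (star arms at `star_fraction` of the
#' mature mean). Reads are the arm sequence with optional isomiR jitter -
#' 5' offsets in -3..+2 and 3' offsets in -2..+5 (strand orientation),
#' truncated so every isomiR stays inside the clustering window of the
#' modal read and inside the 18-30 nt size selection. The 3' adapter is
#' appended and the read truncated to the instrument read length. Optional
#' contaminant-fragment and uniform-random degradation reads are added.
#'
#' @param genome,truth Output of [make_genome()].
#' @param profile Profile from [default_profile()].
#' @param out_dir Directory for the FASTQ files (created).
#' @param adapter 3' adapter sequence.
#' @param read_len Instrument read length (nt). Must leave at least the
#'   minimum adapter overlap (8 nt) beyond the longest size-selected insert
#'   (30 nt), so every genuine small-RNA read is trimmable.
#' @param star_fraction Star-arm abundance relative to the mature arm.
#' @param isomir_prob Probability that a read is a jittered isomiR.
#' @param contaminants Optional contaminant table (`id`, `seq`); fragments
#'   of these are spiked in at `contam_frac` of the arm reads.
#' @param contam_frac,degradation_frac Spike-in fractions.
#' @param seed Integer RNG seed.
#' @return list: `manifest` (data.frame `library`, `treatment`,
#'   `replicate`, `path`, `n_reads`) and `truth_counts` (data.frame
#'   `mirna_id`, `arm`, `library`, `count` of planted modal+isomiR reads).
#' @export
simulate_reads <- function(genome, truth, profile, out_dir,
                           adapter = "CGCCTTGGCCGTACAGCAG", read_len = 40L,
                           star_fraction = 0.1, isomir_prob = 0,
                           contaminants = NULL, contam_frac = 0,
                           degradation_frac = 0, seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  libs <- expand.grid(replicate = seq_len(profile$replicates),
                      treatment = profile$treatments,
                      stringsAsFactors = FALSE)[, 2:1]
  libs$library <- sprintf("%s_r%d", libs$treatment, libs$replicate)
  manifest <- list(); truth_counts <- list()
  chrom_seq <- stats::setNames(genome$seq, genome$id)
  arm_read <- function(h, which_arm, o5, o3) {
    # strand-oriented interval of the (possibly jittered) arm read
    if (which_arm == "mature") {
      s <- truth$mature_start[h]; e <- truth$mature_end[h]
    } else {
      s <- truth$star_start[h]; e <- truth$star_end[h]
    }
    if (truth$strand[h] == "+") {
      gs <- s + o5; ge <- e + o3
    } else {
      gs <- s - o3; ge <- e - o5
    }
    frag <- substr(chrom_seq[[truth$chrom[h]]], gs + 1L, ge)
    if (truth$strand[h] == "-") revcomp(frag) else frag
  }
  for (li in seq_len(nrow(libs))) {
    treatment <- libs$treatment[li]
    reads <- character(0)
    for (h in seq_len(nrow(truth))) {
      for (which_arm in c("mature", "star")) {
        mu <- profile$means[h, treatment] *
          if (which_arm == "star") star_fraction else 1
        if (mu <= 0) next
        cnt <- rcount(1, mu, profile$dispersion)
        if (cnt == 0) {
          truth_counts[[length(truth_counts) + 1L]] <- data.frame(
            mirna_id = truth$mirna_id[h], arm = which_arm,
            library = libs$library[li], count = 0L)
          next
        }
        is_iso <- stats::runif(cnt) < isomir_prob
        arm_len <- if (which_arm == "mature")
          nchar(truth$mature_seq[h]) else nchar(truth$star_seq[h])
        o5 <- integer(cnt); o3 <- integer(cnt)
        n_iso <- sum(is_iso)
        if (n_iso) {
          cand <- expand.grid(o5 = -3:2, o3 = -2:5)
          cand <- cand[!(cand$o5 == 0 & cand$o3 == 0), ]
          len <- arm_len - cand$o5 + cand$o3
          cand <- cand[len >= 18 & len <= 30, ]
          pick <- cand[sample.int(nrow(cand), n_iso, replace = TRUE), ]
          o5[is_iso] <- pick$o5; o3[is_iso] <- pick$o3
        }
        combo <- paste(o5, o3)
        for (cb in unique(combo)) {
          n_cb <- sum(combo == cb)
          off <- as.integer(strsplit(cb, " ")[[1]])
          ins <- arm_read(h, which_arm, off[1], off[2])
          reads <- c(reads, rep(ins, n_cb))
        }
        truth_counts[[length(truth_counts) + 1L]] <- data.frame(
          mirna_id = truth$mirna_id[h], arm = which_arm,
          library = libs$library[li], count = as.integer(cnt))
      }
    }
    n_arm <- length(reads)
    if (!is.null(contaminants) && contam_frac > 0 && nrow(contaminants)) {
      n_c <- round(contam_frac * n_arm)
      if (n_c > 0) {
        src <- sample.int(nrow(contaminants), n_c, replace = TRUE)
        len <- sample(18:30, n_c, replace = TRUE)
        maxs <- nchar(contaminants$seq[src]) - len + 1L
        st <- 1L + floor(stats::runif(n_c) * pmax(1L, maxs))
        reads <- c(reads, substr(contaminants$seq[src], st, st + len - 1L))
      }
    }
    if (degradation_frac > 0) {
      n_d <- round(degradation_frac * n_arm)
      if (n_d > 0) {
        reads <- c(reads, vapply(sample(18:30, n_d, replace = TRUE),
                                 random_seq, character(1)))
      }
    }
    raw <- substr(paste0(reads, adapter), 1L, read_len)
    recs <- data.frame(id = sprintf("%s_%06d", libs$library[li],
                                    seq_along(raw)),
                       seq = raw, qual = strrep("I", nchar(raw)),
                       stringsAsFactors = FALSE)
    path <- file.path(out_dir, paste0(libs$library[li], ".fastq"))
    write_fastq(recs, path)
    manifest[[li]] <- data.frame(library = libs$library[li],
                                 treatment = treatment,
                                 replicate = libs$replicate[li],
                                 path = path, n_reads = nrow(recs),
                                 stringsAsFactors = FALSE)
  }
  list(manifest = do.call(rbind, manifest),
       truth_counts = do.call(rbind, truth_counts))
}

#' Generate a synthetic contaminant ncRNA set
#'
#' Random stand-ins for rRNA/tRNA/repeat contaminant databases; fragments
#' of these can be spiked into simulated libraries and are removed by the
#' contaminant filter.
#'
#' @param n Number of contaminant sequences.
#' @param len Length of each (nt).
#' @param seed Integer RNG seed.
#' @return data.frame `id`, `seq`.
#' @export
make_contaminants <- function(n = 5L, len = 120L, seed = 99L) {
  set.seed(seed)
  data.frame(id = sprintf("ncrna%02d", seq_len(n)),
             seq = vapply(seq_len(n), function(.) random_seq(len),
                          character(1)),
             stringsAsFactors = FALSE)
}

#' Simulate target transcripts and coupled expression profiles
#'
#' Each planted miRNA receives one target transcript containing a site
#' whose duplex with the miRNA is perfectly complementary (expectation 0)
#' unless `site_gu_edits` wobbles are planted. Target expression over the
#' four treatments is an exact affine map of the miRNA's relative
#' expression - decreasing for inverse pairs (canonical repression, Pearson
#' r = -1 in the noiseless case), increasing for decoupled pairs (r = +1) -
#' plus optional Gaussian noise. The slope is shrunk per pair so expression
#' never goes negative, keeping the map exactly affine. The target of the
#' `redox_rescued` hairpin carries the planted key-gene signature
#' (expression high under NaCl+TU, low under TU alone).
#'
#' @param truth Truth table from [make_genome()].
#' @param profile Profile from [default_profile()].
#' @param n_decoupled Number of decoupled pairs (taken from `salt_down`
#'   or `flat` hairpins so they never out-rank the key gene).
#' @param transcript_len Transcript length (nt).
#' @param slope Nominal slope of the affine coupling map.
#' @param floor Minimum relative expression reachable by the map.
#' @param noise_sd Gaussian noise added to target profiles.
#' @param site_gu_edits Number of G:U wobbles planted in each target site
#'   (outside the central positions).
#' @param organ Organ label for the expression table.
#' @param seed Integer RNG seed.
#' @return list: `transcripts` (data.frame `id`, `seq`), `expression`
#'   (data.frame `entity_id`, `type`, `organ`, `control`, `nacl`,
#'   `nacl_tu`, `tu`), `target_map` (data.frame `mirna_id`, `target_id`,
#'   `site_start`, `site_end`, `intended_sign`, `is_key`).
#' @export
simulate_targets <- function(truth, profile, n_decoupled = 3L,
                             transcript_len = 300L, slope = 0.95,
                             floor = 0.05, noise_sd = 0,
                             site_gu_edits = 0L, organ = "root",
                             seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  decoupled_pool <- which(profile$pattern %in% c("salt_down", "flat"))
  decoupled <- utils::head(decoupled_pool, n_decoupled)
  transcripts <- list(); expr <- list(); tmap <- list()
  for (h in seq_len(n)) {
    mid <- truth$mirna_id[h]
    tid <- sprintf("gene%02d", h)
    mature <- truth$mature_seq[h]
    site <- revcomp(mature)
    if (site_gu_edits > 0) {
      # A in the site faces a T/U of the miRNA; A->G keeps a (U:G) wobble.
      # Site position j faces miRNA position (len - j + 1); avoid 9-11.
      w <- nchar(site)
      apos <- which(seq_chars(site) == "A")
      apos <- apos[!((w - apos + 1L) %in% 9:11)]
      for (p in utils::head(sample(apos), site_gu_edits)) {
        substr(site, p, p) <- "G"
      }
    }
    w <- nchar(site)
    pos <- sample(seq(30L, transcript_len - 30L - w), 1)  # 1-based
    tseq <- random_seq(transcript_len)
    substr(tseq, pos, pos + w - 1L) <- site
    x <- profile$means[h, ] / profile$means[h, "control"]
    sgn <- if (h %in% decoupled) 1 else -1
    spread <- max(max(x) - 1, 1 - min(x), 1e-9)
    b <- min(slope, (1 - floor) / spread)
    y <- 1 + sgn * b * (x - 1)
    if (noise_sd > 0) y <- pmax(floor / 2, y + stats::rnorm(4, 0, noise_sd))
    transcripts[[h]] <- data.frame(id = tid, seq = tseq,
                                   stringsAsFactors = FALSE)
    expr[[2 * h - 1]] <- data.frame(entity_id = mid, type = "mirna",
                                    organ = organ, control = x[1],
                                    nacl = x[2], nacl_tu = x[3], tu = x[4],
                                    stringsAsFactors = FALSE)
    expr[[2 * h]] <- data.frame(entity_id = tid, type = "target",
                                organ = organ, control = y[1], nacl = y[2],
                                nacl_tu = y[3], tu = y[4],
                                stringsAsFactors = FALSE)
    tmap[[h]] <- data.frame(mirna_id = mid, target_id = tid,
                            site_start = pos - 1L, site_end = pos - 1L + w,
                            intended_sign = sgn,
                            is_key = profile$pattern[h] == "redox_rescued",
                            stringsAsFactors = FALSE)
  }
  list(transcripts = do.call(rbind, transcripts),
       expression = do.call(rbind, expr),
       target_map = do.call(rbind, tmap))
}
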