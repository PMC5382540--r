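test_that("genome generation is deterministic and plants hairpins faithfully", {
  g1 <- make_genome(n_chrom = 2, chrom_len = 9000, n_hairpins = 8, seed = 5)
  g2 <- make_genome(n_chrom = 2, chrom_len = 9000, n_hairpins = 8, seed = 5)
  expect_identical(g1, g2)
  tr <- g1$truth
  expect_equal(nrow(tr), 8)
  # positions strictly increasing per chromosome, spacing respected
  for (ch in unique(tr$chrom)) {
    s <- tr[tr$chrom == ch, ]
    expect_true(all(diff(s$start) > 0))
    if (nrow(s) > 1) expect_true(all(s$start[-1] - s$end[-nrow(s)] >= 300))
  }
  # the genome carries the mature sequence at the recorded interval
  for (h in seq_len(nrow(tr))) {
    g <- g1$genome$seq[g1$genome$id == tr$chrom[h]]
    frag <- substr(g, tr$mature_start[h] + 1, tr$mature_end[h])
    if (tr$strand[h] == "-") frag <- saltmir:::revcomp(frag)
    expect_equal(frag, tr$mature_seq[h])
  }
  expect_true(all(nchar(tr$mature_seq) >= 20 & nchar(tr$mature_seq) <= 24))
})

test_that("zero hairpins give a pure random genome with empty truth", {
  g <- make_genome(n_chrom = 1, chrom_len = 2000, n_hairpins = 0, seed = 2)
  expect_equal(nrow(g$truth), 0)
  expect_equal(nchar(g$genome$seq), 2000)
})

test_that("infeasible hairpin packing errors out", {
  expect_error(make_genome(n_chrom = 1, chrom_len = 900, n_hairpins = 5,
                           seed = 1), "packing")
})

test_that("read simulation is reproducible and respects the size filters", {
  gen <- make_genome(n_chrom = 1, chrom_len = 6000, n_hairpins = 4, seed = 5)
  prof <- default_profile(gen$truth, base_depth = 50)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_reads(gen$genome, gen$truth, prof, d1, isomir_prob = 0.3,
                       seed = 6)
  s2 <- simulate_reads(gen$genome, gen$truth, prof, d2, isomir_prob = 0.3,
                       seed = 6)
  for (i in seq_len(nrow(s1$manifest))) {
    expect_identical(readLines(s1$manifest$path[i]),
                     readLines(s2$manifest$path[i]))
  }
  # trimmed inserts stay inside the 18-30 nt size selection
  cfg <- pipeline_config()
  for (p in s1$manifest$path) {
    reads <- read_fastq(p)
    tr <- trim_adapter(reads$seq, cfg$adapter)
    expect_true(all(tr$trimmed))
    expect_true(all(nchar(tr$seq) >= 18 & nchar(tr$seq) <= 30))
  }
})

test_that("noiseless reads are exactly the planted arm sequences", {
  gen <- make_genome(n_chrom = 1, chrom_len = 6000, n_hairpins = 4, seed = 5)
  prof <- default_profile(gen$truth, base_depth = 30)
  d <- withr::local_tempdir()
  sim <- simulate_reads(gen$genome, gen$truth, prof, d, isomir_prob = 0,
                        star_fraction = 0, seed = 7)
  cfg <- pipeline_config()
  planted <- gen$truth$mature_seq
  for (p in sim$manifest$path) {
    tr <- trim_adapter(read_fastq(p)$seq, cfg$adapter)
    expect_true(all(tr$seq %in% planted))
  }
})

test_that("planted fold changes are recovered at high depth", {
  gen <- make_genome(n_chrom = 2, chrom_len = 20000, n_hairpins = 10,
                     seed = 13)
  prof <- default_profile(gen$truth, base_depth = 10000, dispersion = 0)
  d <- withr::local_tempdir()
  sim <- simulate_reads(gen$genome, gen$truth, prof, d, seed = 14)
  tc <- sim$truth_counts
  up <- gen$truth$mirna_id[prof$pattern == "salt_up"]
  for (id in up) {
    m <- tc[tc$mirna_id == id & tc$arm == "mature", ]
    nacl <- mean(m$count[grepl("^nacl_r", m$library)])
    ctrl <- mean(m$count[grepl("^control", m$library)])
    expect_lt(abs(log2(nacl / ctrl) - 2), 0.3)
  }
})

test_that("coupled targets carry exact affine profiles and perfect sites", {
  gen <- make_genome(n_chrom = 1, chrom_len = 9000, n_hairpins = 6, seed = 5)
  prof <- default_profile(gen$truth)
  tg <- simulate_targets(gen$truth, prof, n_decoupled = 2, seed = 6)
  expr <- tg$expression
  for (k in seq_len(nrow(tg$target_map))) {
    tm <- tg$target_map[k, ]
    x <- as.numeric(expr[expr$entity_id == tm$mirna_id,
                         c("control", "nacl", "nacl_tu", "tu")])
    y <- as.numeric(expr[expr$entity_id == tm$target_id,
                         c("control", "nacl", "nacl_tu", "tu")])
    if (stats::sd(x) == 0) next
    expect_equal(suppressWarnings(pearson_r(x, y)), tm$intended_sign)
    # the planted site scans at expectation 0
    mir <- gen$truth$mature_seq[gen$truth$mirna_id == tm$mirna_id]
    tx <- tg$transcripts[tg$transcripts$id == tm$target_id, ]
    sites <- scan_transcript(tm$mirna_id, mir, tx)
    expect_true(any(sites$site_start == tm$site_start &
                      sites$expectation == 0))
  }
  # exactly one planted key gene, from the redox-rescued hairpin
  expect_equal(sum(tg$target_map$is_key), 1)
})
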