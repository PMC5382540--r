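mirna <- "TGGAGCTCCTCTTCATTCCAA"  # 21 nt
perfect_site <- saltmir:::revcomp(mirna)

test_that("duplex alignment recognises perfect, substituted and bulged sites", {
  d <- align_duplex(mirna, perfect_site)
  expect_true(all(d$table$state == "match"))
  expect_equal(d$expectation, 0)

  sub <- perfect_site
  substr(sub, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                               strsplit(sub, "")[[1]][4])[1]
  d2 <- align_duplex(mirna, sub)
  expect_equal(sum(d2$table$state == "mismatch") +
                 sum(d2$table$state == "wobble"), 1)

  del <- paste0(substr(perfect_site, 1, 9), substr(perfect_site, 11, 21))
  d3 <- align_duplex(mirna, del)
  expect_equal(sum(grepl("^gap", d3$table$state)), 1)
  expect_gte(sum(d3$table$state == "match"), 19)
  expect_equal(d3$expectation, oracle_min_expectation(mirna, del))
})

test_that("expectation scoring applies seed doubling and the hspsize cap", {
  expect_equal(expectation_score(align_duplex(mirna, perfect_site)), 0.0)
  # single G:U at miRNA position 5: 0.5 x 2 (seed doubling) = 1.0
  mir_gu <- mirna
  stopifnot(substr(mir_gu, 5, 5) == "G")
  site_gu <- perfect_site
  p <- nchar(site_gu) - 5 + 1  # site base facing miRNA position 5
  stopifnot(substr(site_gu, p, p) == "C")
  substr(site_gu, p, p) <- "T"
  expect_equal(expectation_score(align_duplex(mirna, site_gu)), 1.0)
  # single mismatch at position 18: outside the seed, not doubled
  site_mm <- perfect_site
  p18 <- nchar(site_mm) - 18 + 1
  mirna18 <- substr(mirna, 18, 18)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(saltmir:::revcomp(mirna18),
                   if (mirna18 == "G") "T", if (mirna18 == "T") "G"))[1]
  substr(site_mm, p18, p18) <- bad
  expect_equal(expectation_score(align_duplex(mirna, site_mm)), 1.0)
  # positions beyond hspsize are unscored
  d <- align_duplex(mirna, perfect_site, hspsize = 20)
  expect_equal(d$table$penalty[21], 0)
})

test_that("central mismatches flag translational inhibition", {
  mm_at <- function(pos) {
    s <- perfect_site
    p <- nchar(s) - pos + 1
    mb <- substr(mirna, pos, pos)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(saltmir:::revcomp(mb),
                     if (mb == "G") "T", if (mb == "T") "G"))[1]
    substr(s, p, p) <- bad
    s
  }
  expect_equal(classify_inhibition(align_duplex(mirna, mm_at(10))),
               "translational")
  expect_equal(classify_inhibition(align_duplex(mirna, mm_at(8))),
               "cleavage")
  expect_equal(classify_inhibition(align_duplex(mirna, perfect_site)),
               "cleavage")
})

test_that("transcript scanning finds planted sites with correct flanks", {
  set.seed(11)
  up <- random_dna(120); down <- random_dna(80)
  tx <- data.frame(id = "t1", seq = paste0(up, perfect_site, down))
  sites <- scan_transcript("mirX", mirna, tx)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_start, 120)
  expect_equal(sites$site_end, 120 + 21)
  expect_equal(sites$expectation, 0.0)
  expect_equal(sites$mode, "cleavage")
  expect_equal(sites$flank_up_seq, substr(up, 121 - 17, 120))
  expect_equal(nchar(sites$flank_down_seq), 13)
  # flank truncation at the transcript start
  tx2 <- data.frame(id = "t2", seq = paste0(substr(up, 116, 120),
                                            perfect_site, down))
  s2 <- scan_transcript("mirX", mirna, tx2)
  expect_equal(s2$flank_up_seq, substr(up, 116, 120))
})

test_that("sites beyond the expectation cutoff are not emitted", {
  # two seed mismatches cost 2 x 2.0 = 4.0 > 2.0
  s <- perfect_site
  for (pos in c(4, 7)) {
    p <- nchar(s) - pos + 1
    mb <- substr(mirna, pos, pos)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(saltmir:::revcomp(mb),
                     if (mb == "G") "T", if (mb == "T") "G"))[1]
    substr(s, p, p) <- bad
  }
  tx <- data.frame(id = "t1", seq = paste0(random_dna(50), s,
                                           random_dna(50)))
  expect_equal(nrow(scan_transcript("mirX", mirna, tx)), 0)
})

test_that("random transcripts rarely contain sites at cutoff 2.0", {
  set.seed(21)
  empty <- 0
  for (k in 1:20) {
    tx <- data.frame(id = "t", seq = random_dna(1000))
    mir <- random_dna(21)
    if (nrow(scan_transcript("m", mir, tx)) == 0) empty <- empty + 1
  }
  expect_gte(empty, 19)
})

test_that("additional mismatches never lower the expectation", {
  set.seed(31)
  for (k in 1:60) {
    mir <- random_dna(21)
    site <- saltmir:::revcomp(mir)
    # random starting perturbation
    n0 <- sample(0:1, 1)
    if (n0) {
      p <- sample(21, 1)
      substr(site, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    e0 <- align_duplex(mir, site)$expectation
    # mutate one currently matched site position
    d <- align_duplex(mir, site)
    matched <- which(d$table$state == "match")
    if (!length(matched)) next
    mp <- d$table$mir_pos[sample(matched, 1)]
    sp <- nchar(site) - mp + 1
    cur <- substr(site, sp, sp)
    substr(site, sp, sp) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    e1 <- align_duplex(mir, site)$expectation
    expect_gte(e1, e0 - 1e-9)
  }
})

test_that("duplex scoring agrees with exhaustive alignment enumeration", {
  set.seed(41)
  for (k in 1:100) {
    m <- sample(8:12, 1)
    mir <- random_dna(m)
    w <- m + sample(-1:1, 1)
    window <- random_dna(w)
    got <- align_duplex(mir, window)$expectation
    want <- oracle_min_expectation(mir, window)
    expect_equal(got, want, info = paste(mir, window))
  }
})

test_that("overlapping emitted sites merge keeping the lower expectation", {
  # a perfect site; windows shifted by one overlap it with higher scores
  tx <- data.frame(id = "t1",
                   seq = paste0(random_dna(40), perfect_site, random_dna(40)))
  sites <- scan_transcript("mirX", mirna, tx)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$expectation, 0.0)
})

test_that("per-miRNA site reporting is capped", {
  tx <- data.frame(id = sprintf("t%d", 1:5),
                   seq = vapply(1:5, function(i)
                     paste0(random_dna(30), perfect_site, random_dna(30)),
                     character(1)))
  sites <- scan_transcript("mirX", mirna, tx, max_sites = 3)
  expect_equal(nrow(sites), 3)
})
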