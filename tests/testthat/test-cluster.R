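mk_aln <- function(...) {
  df <- data.frame(...)
  if (is.null(df$seq)) df$seq <- strrep("A", df$end - df$start)
  df
}

test_that("reads at identical positions merge into one cluster", {
  aln <- mk_aln(seq = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"),
                total = c(10L, 5L), chrom = "c1", start = 100L, end = 121L,
                strand = "+")
  cl <- cluster_reads(aln)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$total_count, 15L)
  expect_equal(cl$clusters$founder_seq, "ACGTACGTACGTACGTACGTA")
})

test_that("the flanked window rule decides membership at 1 nt precision", {
  # founder [100,121,+): window [97,126); read [98,122) fits, [96,117) not
  aln <- mk_aln(total = c(10L, 3L, 2L), chrom = "c1",
                start = c(100L, 98L, 96L), end = c(121L, 122L, 117L),
                strand = "+")
  cl <- cluster_reads(aln, up_flank = 3L, down_flank = 5L)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$members$cluster_id[cl$members$start == 98], "cl0001")
  expect_equal(cl$members$cluster_id[cl$members$start == 96], "cl0002")
  # cluster coordinates stay those of the founding read
  expect_equal(cl$clusters$start[1], 100L)
  expect_equal(cl$clusters$end[1], 121L)
})

test_that("windows are computed in strand orientation", {
  # minus strand: window [start - down_flank, end + up_flank)
  aln <- mk_aln(total = c(10L, 3L), chrom = "c1",
                start = c(100L, 96L), end = c(121L, 117L), strand = "-")
  cl <- cluster_reads(aln, up_flank = 3L, down_flank = 5L)
  # window [95,124): read [96,117) fits on the minus strand
  expect_equal(nrow(cl$clusters), 1)
  aln$strand <- "+"
  expect_equal(nrow(cluster_reads(aln)$clusters), 2)
})

test_that("every alignment belongs to exactly one cluster", {
  set.seed(77)
  n <- 60
  aln <- data.frame(total = sample(1:50, n, replace = TRUE), chrom = "c1",
                    start = sort(sample(0:1900, n)),
                    strand = sample(c("+", "-"), n, replace = TRUE))
  aln$end <- aln$start + sample(20:24, n, replace = TRUE)
  aln$seq <- vapply(aln$end - aln$start, random_dna, character(1))
  cl <- cluster_reads(aln)
  expect_equal(nrow(cl$members), n)
  expect_false(any(is.na(cl$members$cluster_id)))
  expect_equal(sum(cl$clusters$total_count), sum(aln$total))
  expect_equal(sum(cl$clusters$n_members), n)
})

test_that("clustering matches the literal greedy transcription", {
  set.seed(101)
  for (trial in 1:25) {
    n <- sample(5:50, 1)
    aln <- data.frame(
      total = sample(1:30, n, replace = TRUE),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(0:1950, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE))
    aln$end <- aln$start + sample(18:30, n, replace = TRUE)
    aln$seq <- vapply(aln$end - aln$start, random_dna, character(1))
    got <- cluster_reads(aln)
    want <- oracle_cluster(aln)
    expect_equal(nrow(got$clusters), nrow(want$founders))
    # same read order and same partition
    expect_equal(got$members$seq, want$aln$seq)
    expect_equal(as.integer(factor(got$members$cluster_id,
                                   levels = unique(got$members$cluster_id))),
                 as.integer(factor(want$assign,
                                   levels = unique(want$assign))))
  }
})

test_that("equal-count read order does not change the clustering", {
  aln <- mk_aln(total = c(5L, 5L, 5L), chrom = "c1",
                start = c(100L, 300L, 102L), end = c(121L, 321L, 123L),
                strand = "+",
                seq = c("AAATTTAAATTTAAATTTAAA", "CCCGGGCCCGGGCCCGGGCCC",
                        "GGGTTTGGGTTTGGGTTTGGG"))
  a <- cluster_reads(aln)
  b <- cluster_reads(aln[c(3, 1, 2), ])
  expect_equal(a$clusters, b$clusters)
})

test_that("cluster pairing enforces the strict 150 nt rule", {
  base <- mk_aln(total = c(10L, 8L), chrom = "c1",
                 start = c(100L, 0L), end = c(121L, 0L), strand = "+",
                 seq = c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"))
  for (gap in c(40L, 149L, 150L)) {
    base$start[2] <- 121L + gap
    base$end[2] <- base$start[2] + 21L
    cand <- pair_clusters(cluster_reads(base)$clusters)
    if (gap < 150) {
      expect_equal(nrow(cand), 1)
      expect_equal(cand$gap, gap)
    } else {
      expect_equal(nrow(cand), 0)
    }
  }
})

test_that("chained clusters pair nearest-first with a left tie-break", {
  # A --60-- B --60-- C: B pairs A, C stays unpaired
  aln <- mk_aln(total = c(9L, 8L, 7L), chrom = "c1",
                start = c(100L, 181L, 262L), end = c(121L, 202L, 283L),
                strand = "+",
                seq = c("AAATTTAAATTTAAATTTAAA", "CCCGGGCCCGGGCCCGGGCCC",
                        "GGGTTTGGGTTTGGGTTTGGG"))
  cand <- pair_clusters(cluster_reads(aln)$clusters)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$mature_start, 100L)
  expect_equal(cand$star_start, 181L)
})

test_that("overlapping clusters are never paired", {
  aln <- mk_aln(total = c(9L, 8L), chrom = "c1",
                start = c(100L, 110L), end = c(121L, 131L), strand = "+",
                seq = c("AAATTTAAATTTAAATTTAAA", "CCCGGGCCCGGGCCCGGGCCC"))
  cand <- pair_clusters(cluster_reads(aln, 0L, 0L)$clusters)
  expect_equal(nrow(cand), 0)
  expect_equal(attr(cand, "n_overlapping_pairs"), 1L)
})

test_that("the mature arm is the higher-count cluster", {
  aln <- mk_aln(total = c(3L, 30L), chrom = "c1",
                start = c(100L, 160L), end = c(121L, 182L), strand = "+",
                seq = c("AAATTTAAATTTAAATTTAAA", "CCCGGGCCCGGGCCCGGGCCCG"))
  cand <- pair_clusters(cluster_reads(aln)$clusters)
  expect_equal(cand$mature_seq, "CCCGGGCCCGGGCCCGGGCCCG")
  expect_equal(cand$star_seq, "AAATTTAAATTTAAATTTAAA")
})

test_that("mature length filtering is inclusive at 20 and 24 nt", {
  cand <- data.frame(candidate_id = sprintf("c%d", 1:4),
                     mature_seq = strrep("A", c(19, 20, 24, 25)))
  kept <- filter_candidate_length(cand, 20L, 24L)
  expect_equal(kept$candidate_id, c("c2", "c3"))
  expect_equal(attr(kept, "n_dropped_length"), 2L)
})

test_that("quantification sums member counts per library and conserves reads", {
  # two isomiRs 60/40 in lib0 within one cluster, star 10 in lib1
  reads <- c(rep("ACGTACGTACGTACGTACGTA", 60),
             rep("ACGTACGTACGTACGTACG", 40),
             rep("TTTTCCCCGGGGAAAATTTTC", 10))
  libi <- c(rep(1L, 100), rep(2L, 10))
  ur <- collapse_unique(reads, libi, c("lib0", "lib1"))
  aln <- data.frame(seq = ur$seq, total = ur$total, chrom = "c1",
                    start = c(100L, 100L, 160L),
                    end = c(100L, 100L, 160L) + nchar(ur$seq),
                    strand = "+")
  cl <- cluster_reads(aln)
  cand <- pair_clusters(cl$clusters)
  expect_equal(nrow(cand), 1)
  q <- quantify(cand, cl, ur)
  expect_equal(unname(q$counts[1, ]), c(100L, 0L))  # isomiRs sum to 100
  expect_false(q$flags$multi_placement)
})
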