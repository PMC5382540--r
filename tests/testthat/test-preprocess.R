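adapter <- "CGCCTTGGCCGTACAGCAG"

test_that("adapter trimming honours the minimum 8 nt overlap rule", {
  insert <- "TGGAGCTCCTATCATTCCAAT"
  # full adapter appended
  tr <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(tr$seq, insert)
  expect_true(tr$trimmed)
  # exactly the first 8 adapter nt at the 3' end: trimmed
  tr8 <- trim_adapter(paste0(insert, substr(adapter, 1, 8)), adapter)
  expect_equal(tr8$seq, insert)
  expect_true(tr8$trimmed)
  # only 7 adapter nt: below the minimum overlap, kept and flagged
  tr7 <- trim_adapter(paste0(insert, substr(adapter, 1, 7)), adapter)
  expect_equal(tr7$seq, paste0(insert, substr(adapter, 1, 7)))
  expect_false(tr7$trimmed)
  # internal occurrence: cut at the leftmost qualifying hit
  s <- paste0("ACGTACGTAC", adapter, "TTTTTTTTTT")
  expect_equal(trim_adapter(s, adapter)$seq, "ACGTACGTAC")
})

test_that("a spurious probe hit is skipped when the extension mismatches", {
  # the first 8 adapter nt occur early, but the following base breaks the
  # adapter prefix and the read continues past it; the genuine full-length
  # hit further right must be used
  decoy <- paste0(substr(adapter, 1, 8), "TTTT")
  stopifnot(substr(decoy, 9, 9) != substr(adapter, 9, 9))
  s <- paste0("ACGTT", decoy, "GGCCA", adapter)
  tr <- trim_adapter(s, adapter)
  expect_equal(tr$seq, paste0("ACGTT", decoy, "GGCCA"))
})

test_that("size and contaminant filters apply in order with full tallies", {
  contams <- data.frame(id = "trna1",
                        seq = "GGGCGTGTGGCGTAGTCGGTAGCGCGCTCCCTTAGCATGGGAGAG")
  reads <- c(strrep("A", 17),                      # too short
             strrep("A", 31),                      # too long
             substr(contams$seq, 3, 23),           # tRNA fragment, 21 nt
             saltmir:::revcomp(substr(contams$seq, 3, 25)),  # minus strand
             "TGGAGCTCCTATCATTCCAATCC")            # clean 23-mer
  fl <- filter_reads(reads, 18, 30, contams)
  expect_equal(unname(fl$tally),
               c(5L, 2L, 2L, 1L))
  expect_equal(fl$kept, "TGGAGCTCCTATCATTCCAATCC")
  # conservation: input = kept + per-filter drops
  expect_equal(fl$tally[["input"]],
               fl$tally[["kept"]] + fl$tally[["dropped_length"]] +
                 fl$tally[["dropped_contaminant"]])
})

test_that("collapsing counts per library and breaks ties lexicographically", {
  reads <- c(rep("ACGTACGTACGTACGTACGTA", 3), "ACGTACGTACGTACGTACGTA",
             "TTTTACGTACGTACGTACGTA")
  libi <- c(1L, 1L, 1L, 2L, 2L)
  ur <- collapse_unique(reads, libi, c("lib0", "lib1"))
  expect_equal(ur$lib0, c(3L, 0L))
  expect_equal(ur$lib1, c(1L, 1L))
  expect_equal(sum(ur$total), length(reads))  # multiset size conserved
  # equal totals: lexicographically smaller sequence first
  ur2 <- collapse_unique(c("TTTT", "AAAA"), c(1L, 1L), "lib0")
  expect_equal(ur2$seq, c("AAAA", "TTTT"))
  # all distinct: unit vectors
  ur3 <- collapse_unique(c("AAAA", "CCCC"), c(1L, 2L), c("a", "b"))
  expect_true(all(ur3$total == 1L))
})

test_that("exact mapping agrees with a naive scan oracle", {
  set.seed(401)
  genome <- data.frame(id = c("c1", "c2"),
                       seq = c(random_dna(3000), random_dna(2000)))
  # reads: planted forward, planted reverse-complement, random
  reads <- character(0)
  for (k in 1:40) {
    s <- sample(2900, 1)
    reads <- c(reads, substr(genome$seq[1], s, s + 20))
  }
  for (k in 1:40) {
    s <- sample(1900, 1)
    reads <- c(reads, saltmir:::revcomp(substr(genome$seq[2], s, s + 21)))
  }
  reads <- c(reads, vapply(rep(21, 20), random_dna, character(1)))
  ur <- collapse_unique(reads, rep(1L, length(reads)), "lib0")
  aln <- map_exact(ur, genome)
  for (r in seq_len(nrow(ur))) {
    expected <- oracle_scan_map(ur$seq[r], genome)
    got <- aln[aln$seq == ur$seq[r], c("chrom", "start", "end", "strand")]
    if (is.null(expected)) {
      expect_equal(nrow(got), 0)
    } else {
      expected <- expected[order(expected$chrom, expected$start,
                                 expected$strand), ]
      got <- got[order(got$chrom, got$start, got$strand), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(expected)))
      expect_true(all(aln$n_placements[aln$seq == ur$seq[r]] ==
                        nrow(expected)))
    }
  }
})

test_that("multi-mapped reads are reported at every placement", {
  g <- paste0(random_dna(50), "ACGTACGTACGTACGTACGTA", random_dna(50),
              "ACGTACGTACGTACGTACGTA", random_dna(50))
  ur <- collapse_unique("ACGTACGTACGTACGTACGTA", 1L, "lib0")
  aln <- map_exact(ur, data.frame(id = "c1", seq = g))
  expect_gte(nrow(aln), 2)
  expect_true(all(aln$n_placements == nrow(aln)))
})
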