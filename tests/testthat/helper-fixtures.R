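# Shared fixtures. The standard fixture (20 planted hairpins, depth 1000
# per mature arm, no isomiR noise) is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

standard_fixture <- function() {
  if (!is.null(.fixture_env$std)) return(.fixture_env$std)
  gen <- make_genome(n_chrom = 2L, chrom_len = 20000L, n_hairpins = 20L,
                     seed = 7L)
  profile <- default_profile(gen$truth, replicates = 2L, base_depth = 1000)
  dir <- file.path(tempdir(), "saltmir_std_fixture")
  sim <- simulate_reads(gen$genome, gen$truth, profile,
                        file.path(dir, "reads"), seed = 8L)
  targets <- simulate_targets(gen$truth, profile, seed = 9L)
  .fixture_env$std <- list(gen = gen, profile = profile, sim = sim,
                           targets = targets, dir = dir)
  .fixture_env$std
}

standard_run <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  fx <- standard_fixture()
  out <- file.path(fx$dir, "out")
  cfg <- pipeline_config(rng_seed = 11L)
  report <- run_pipeline(cfg, list(
    fastq_manifest = fx$sim$manifest, genome = fx$gen$genome,
    transcripts = fx$targets$transcripts,
    expression = fx$targets$expression), out)
  .fixture_env$run <- list(out = out, report = report, cfg = cfg)
  .fixture_env$run
}

# A tiny deterministic hairpin: mature + A/C loop + near-revcomp star.
toy_hairpin <- function(mature = "TGGAGCTCCTATCATTCCAAT", loop = 12L,
                        gu = 1L) {
  star <- saltmir:::revcomp(mature)
  if (gu > 0) {
    elig <- which(strsplit(star, "")[[1]] %in% c("A", "C"))
    p <- elig[ceiling(length(elig) / 2)]
    b <- substr(star, p, p)
    substr(star, p, p) <- if (b == "C") "T" else "G"
  }
  list(mature = mature, star = star,
       seq = paste0(mature, strrep("AC", ceiling(loop / 2)), star))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
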