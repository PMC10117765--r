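# Shared fixtures, built in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# full default simulation (the study conditions): genome + reads + quant
default_sim <- function() {
  memo("default_sim", {
    cfg <- sim_config()
    genome <- make_genome(cfg)
    reads <- simulate_reads(genome, cfg)
    pairing <- data.frame(replicate = 1:2,
                          ribo_sample = c("ribo_1", "ribo_2"),
                          rna_sample = c("rna_1", "rna_2"))
    feats <- rbind(
      genome$truth[, c("feature_id", "replicon_id", "strand", "start",
                       "end", "feature_class")],
      genome$rnas[, c("feature_id", "replicon_id", "strand", "start",
                      "end", "feature_class")])
    quants <- quantify_features(feats, reads, pairing)
    list(config = cfg, genome = genome, reads = reads, pairing = pairing,
         quants = quants)
  })
}

# small, fast simulation for tests that only need structure
small_sim <- function() {
  memo("small_sim", {
    cfg <- sim_config(seed = 5L,
                      replicon_lengths = c(chr = 40000L, pA = 20000L),
                      n_translated_cds = 12L, n_translated_sorfs = 8L,
                      n_untranslated_srnas = 4L, n_hkrnas = 3L,
                      n_uorfs = 2L, n_antisense_sorfs = 2L,
                      library_size = 60000L)
    genome <- make_genome(cfg)
    reads <- simulate_reads(genome, cfg)
    list(config = cfg, genome = genome, reads = reads)
  })
}

random_reads <- function(n, rep_lens, seed = 1L) {
  set.seed(seed)
  rid <- sample(names(rep_lens), n, replace = TRUE)
  len <- sample(20:45, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(rep_lens[[rid[[i]]]] - len[[i]], 1L) - 1L, 0L)
  data.frame(replicon_id = rid, strand = sample(c("+", "-"), n, TRUE),
             start = start, end = start + len,
             library = "RIBO", sample_id = "s1",
             stringsAsFactors = FALSE)
}

# quant-like table with randomized values for filter-oracle tests
random_quants <- function(n, seed = 99L) {
  set.seed(seed)
  data.frame(
    feature_id = sprintf("f%04d", seq_len(n)),
    mean_te = ifelse(runif(n) < 0.05, NA_real_, round(runif(n, 0, 2), 2)),
    rpkm_ribo_1 = round(runif(n, 0, 40), 1),
    rpkm_ribo_2 = round(runif(n, 0, 40), 1),
    rpkm_rna_1 = round(runif(n, 0, 40), 1),
    rpkm_rna_2 = round(runif(n, 0, 40), 1),
    stringsAsFactors = FALSE)
}
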