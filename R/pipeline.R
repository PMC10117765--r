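# End-to-end pipeline binding: simulate -> coverage -> quantify ->
# metagene -> sORF calls -> custom search DB -> peptide evidence ->
# acceptance, with a reproducibility manifest. The exported functions are
# the entry points; `run_pipeline()` chains them the way a command-line
# driver would.

#' Run the full translatome-mapping pipeline on simulated data
#'
#' Executes every stage on a synthetic dataset and writes each stage's
#' table plus a manifest (configuration echo, seed, output file hashes)
#' sufficient to reproduce the run.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()]; its seed controls all randomness.
#' @param thresholds A [sorf_thresholds()].
#' @param params A [curation_params()].
#' @param protease Protease for the PSM/DB stage.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         thresholds = sorf_thresholds(),
                         params = curation_params(),
                         protease = "trypsin") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(config)
  reads <- simulate_reads(genome, config)
  write_simulation(genome, reads, out_dir)

  pairing <- data.frame(replicate = seq_len(config$n_replicates),
                        ribo_sample = sprintf("ribo_%d",
                                              seq_len(config$n_replicates)),
                        rna_sample = sprintf("rna_%d",
                                             seq_len(config$n_replicates)))

  # quantification over truth ORFs, untranslated RNAs and candidates
  feats <- rbind(
    genome$truth[, c("feature_id", "replicon_id", "strand", "start", "end",
                     "feature_class")],
    if (!is.null(genome$rnas))
      genome$rnas[, c("feature_id", "replicon_id", "strand", "start",
                      "end", "feature_class")])
  quants <- quantify_features(feats, reads, pairing)
  write_quant_table(quants, file.path(out_dir, "quantification.tsv"))
  te_summary <- class_te_summary(quants)
  data.table::fwrite(te_summary, file.path(out_dir, "class_te_summary.tsv"),
                     sep = "\t")

  # metagene on pooled Ribo 5'-end track, annotated CDS starts
  ribo_reads <- reads[reads$library == "RIBO", ]
  five <- build_coverage(
    transform(ribo_reads, sample_id = "ribo_pooled"),
    genome$replicons, mode = "five_prime")
  cds <- genome$truth[genome$truth$feature_class == "CDS" &
                        genome$truth$annotated, ]
  mg <- metagene_profile(five, cds)
  write_metagene(mg, file.path(out_dir, "metagene_5prime.tsv"))

  # min-normalized global tracks (replicate 1) for curation
  tr_r <- build_coverage(reads[reads$sample_id == "ribo_1", ],
                         genome$replicons, mode = "global")
  tr_n <- build_coverage(reads[reads$sample_id == "rna_1", ],
                         genome$replicons, mode = "global")
  mn <- normalize_min(list(tr_r, tr_n))

  # annotated sORFs through the annotated cascade
  ann_sorf_ids <- genome$truth$feature_id[
    genome$truth$feature_class == "sORF" & genome$truth$annotated]
  ann_calls <- filter_annotated_sorfs(
    quants[quants$feature_id %in% ann_sorf_ids, ], thresholds)
  data.table::fwrite(ann_calls,
                     file.path(out_dir, "calls_annotated_sorfs.tsv"),
                     sep = "\t")

  # novel candidates through the full cascade + curation
  cand <- genome$candidates
  qc <- quants[match(cand$feature_id, quants$feature_id), ]
  qc$feature_id <- cand$candidate_id
  calls <- call_sorfs(qc, cand, mn[[1L]], mn[[2L]], thresholds, params)
  calls$context <- vapply(seq_len(nrow(cand)), function(i)
    classify_context(cand[i, ], genome$annotation$features), "")
  data.table::fwrite(calls, file.path(out_dir, "calls_novel_sorfs.tsv"),
                     sep = "\t")

  # Ribo-seq-informed custom database from translated calls + truth annotation
  passed <- cand[calls$verdict != "fail", , drop = FALSE]
  ribo_set <- annotation_set(
    "riboseq", 50L,
    feature_table(passed$candidate_id, passed$replicon_id, passed$strand,
                  passed$start, passed$end,
                  ifelse(passed$aa_length <= 70L, "sORF", "CDS"),
                  source = "riboseq"),
    category = "riboseq")
  truth_cds <- genome$annotation
  clusters <- integrate_annotations(list(truth_cds), ribo_set,
                                    genome$replicons)
  db <- build_db(clusters, protease = protease)
  write_iptgxdb(db, file.path(out_dir, "iptgxdb_custom.fasta"),
                file.path(out_dir, "iptgxdb_custom.gff3"))

  psms <- simulate_psms(genome, protease = protease, config = config)
  decisions <- accept_proteins(clusters, psms)
  data.table::fwrite(decisions, file.path(out_dir, "acceptance_master.tsv"),
                     sep = "\t")

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "class")],
    thresholds = unclass(thresholds), curation = unclass(params),
    protease = protease,
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                               pattern = "\\.(tsv|gff3|fasta)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = genome, reads = reads, quants = quants,
                 te_summary = te_summary, metagene = mg,
                 annotated_calls = ann_calls, novel_calls = calls,
                 clusters = clusters, db = db, psms = psms,
                 decisions = decisions))
}

#' Sensitivity and false-admission of the sORF cascade against truth
#'
#' @param genome A [make_genome()] result.
#' @param novel_calls Calls table from [call_sorfs()] (feature ids =
#'   candidate ids).
#' @return List with `sensitivity` (translated candidates recovered) and
#'   `false_admission` (untranslated candidates passing).
#' @export
recovery_stats <- function(genome, novel_calls) {
  cand <- genome$candidates
  truth_tr <- cand$reparation_called
  pass <- novel_calls$verdict[match(cand$candidate_id,
                                    novel_calls$feature_id)] != "fail"
  list(sensitivity = mean(pass[truth_tr]),
       false_admission = if (any(!truth_tr)) mean(pass[!truth_tr]) else 0)
}
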