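# Deterministic simulator: toy genome, planted transcripts/ORFs, aligned
# Ribo-seq and RNA-seq reads, candidate-ORF score tables and PSM tables,
# with a ground-truth table for recovery tests.
#
# Signal model for ribosome footprints: lengths 27-33 nt (mode 30); footprint
# 5' ends pile up 16 nt upstream of the start codon and 3' ends 16 nt
# downstream of the stop codon (initiating/terminating ribosomes protect
# ~15-16 nt beyond the ORF); the initiation pile-up is strongest for 32 nt
# footprints; body footprints tile the ORF uniformly. RNA-seq fragments tile
# whole transcripts, UTRs included. Untranslated RNAs receive RNA reads only.

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0)), c("A","C","G","T"), paste0)),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under: a
#' scaled-down three-replicon genome (chromosome plus two megaplasmids),
#' footprints of 27-33 nt with the mode at 30 nt, initiation/termination
#' pile-ups extending 16 nt beyond start/stop codons with the strongest
#' initiation enrichment for 32 nt footprints, two replicates and 2e5 reads
#' per library.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines every simulator output.
#' @param replicon_lengths Named integer vector of replicon sizes (nt).
#' @param n_translated_cds,n_translated_sorfs,n_untranslated_srnas,n_hkrnas,
#'   n_uorfs,n_antisense_sorfs Feature counts. Standalone sORFs are split
#'   between annotated and novel by `sorf_annotated_frac`.
#' @param n_operon_genes Genes in the single planted operon (intergenic gaps
#'   of 14 and 12 nt between the first three genes).
#' @param n_duplicated_sorfs Pairs of identical-sequence sORF gene copies
#'   (exercises peptide class 3a).
#' @param sorf_annotated_frac Fraction of standalone translated sORFs placed
#'   in the truth annotation (the rest are novel candidates only).
#' @param leaderless_frac Fraction of standalone sORF transcripts that are
#'   leaderless (transcript starts at the ATG).
#' @param footprint_lengths,footprint_weights Footprint length support and
#'   probability weights (must sum to 1).
#' @param initiation_pileup_extent Protection beyond start/stop codons (nt).
#' @param init_frac,term_frac Fraction of an ORF's footprints in the
#'   initiation / termination pile-up.
#' @param init_boost_length,init_boost_factor Footprint length with the
#'   strongest initiation pile-up and its multiplier on `init_frac`.
#' @param te_meanlog,te_sdlog,te_bounds Log-normal parameters and truncation
#'   bounds for raw translation-efficiency levels of translated features.
#' @param rna_frag_range RNA-seq fragment length range (nt).
#' @param library_size Reads per sample (each library, each replicate).
#' @param n_replicates Paired Ribo/RNA replicates.
#' @param background_rate Expected uniform background RIBO reads per sample
#'   (0 = no noise; used to probe filter specificity).
#' @param n_psm_replicates MS replicates for simulated PSM tables.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       replicon_lengths = c(chr = 120000L, pSymA = 60000L,
                                            pSymB = 40000L),
                       n_translated_cds = 40L,
                       n_translated_sorfs = 20L,
                       n_untranslated_srnas = 10L,
                       n_hkrnas = 6L,
                       n_uorfs = 5L,
                       n_antisense_sorfs = 5L,
                       n_operon_genes = 3L,
                       n_duplicated_sorfs = 1L,
                       sorf_annotated_frac = 0.5,
                       leaderless_frac = 0.25,
                       footprint_lengths = 27:33,
                       footprint_weights = c(0.04, 0.08, 0.16, 0.34,
                                             0.20, 0.12, 0.06),
                       initiation_pileup_extent = 16L,
                       init_frac = 0.12, term_frac = 0.08,
                       init_boost_length = 32L, init_boost_factor = 3,
                       te_meanlog = log(1.4), te_sdlog = 0.3,
                       te_bounds = c(0.8, 3),
                       rna_frag_range = c(25L, 40L),
                       library_size = 200000L,
                       n_replicates = 2L,
                       background_rate = 0,
                       n_psm_replicates = 3L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$footprint_weights) == length(cfg$footprint_lengths),
            abs(sum(cfg$footprint_weights) - 1) < 1e-8,
            all(c(cfg$n_translated_cds, cfg$n_translated_sorfs,
                  cfg$n_untranslated_srnas, cfg$n_uorfs,
                  cfg$n_antisense_sorfs) >= 0),
            cfg$library_size > 0, cfg$n_replicates >= 1,
            cfg$background_rate >= 0)
  structure(cfg, class = "sim_config")
}

random_orf_nt <- function(aa_len, start_weights = c(0.75, 0.18, 0.07)) {
  start <- sample(START_CODONS, 1L, prob = start_weights)
  stopc <- sample(STOP_CODONS, 1L)
  paste0(start,
         paste(sample(SENSE_CODONS, aa_len - 1L, replace = TRUE),
               collapse = ""),
         stopc)
}

# Sequence guaranteed to contain no stop codon in the given frame is not
# needed for UTRs; plain random background.
random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Find a placement window of `len` nt on some replicon avoiding occupied
# intervals (padded); returns list(replicon_id, start) or errors out.
place_interval <- function(len, occ, rep_lens, pad = 40L, margin = 100L,
                           max_tries = 400L) {
  rep_ids <- names(rep_lens)
  w <- as.numeric(rep_lens)
  for (i in seq_len(max_tries)) {
    rid <- sample(rep_ids, 1L, prob = w)
    L <- rep_lens[[rid]]
    if (L - len - 2L * margin <= 0L) next
    s <- sample.int(L - len - 2L * margin, 1L) + margin
    ivs <- occ[[rid]]
    ok <- TRUE
    if (nrow(ivs) > 0L)
      ok <- !any(ivs$start - pad < s + len & ivs$end + pad > s)
    if (ok) return(list(replicon_id = rid, start = s))
  }
  stop("could not place a feature of ", len,
       " nt without forbidden overlap after ", max_tries, " tries")
}

draw_te <- function(n, cfg) {
  x <- stats::rlnorm(n, cfg$te_meanlog, cfg$te_sdlog)
  pmin(pmax(x, cfg$te_bounds[[1L]]), cfg$te_bounds[[2L]])
}

#' Generate a toy genome with planted transcripts and ORFs
#'
#' Plants translated CDS with 5'/3'-UTRs (including one operon whose first
#' intergenic gaps are 14 and 12 nt), standalone translated sORFs of 10-70 aa
#' (a fraction leaderless), upstream ORFs inside host 5'-UTRs, antisense
#' sORFs opposite host 3'-UTRs, untranslated sRNAs carrying decoy ORFs, and
#' untranslated housekeeping RNAs. Identical-sequence sORF gene copies are
#' planted to exercise shared-peptide classification.
#'
#' Planted translation-efficiency values in the truth table are expressed on
#' the RPKM-ratio scale (Ribo RPKM / RNA RPKM): the raw per-feature levels
#' are multiplied by the analytically expected library-composition factor so
#' that the estimand the quantifier measures equals the truth value.
#'
#' @param config A [sim_config()].
#' @return A list with class `sim_genome`: `replicons`, `truth` (per-feature
#'   truth table), `transcripts`, `annotation` (truth [annotation_set()]
#'   with CDS, annotated sORFs, UTRs, sRNA/hkRNA and transcript features) and
#'   `candidates` (novel-ORF score table emulating a predictor's output).
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_lens <- config$replicon_lengths
  seqs <- lapply(rep_lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  occ <- lapply(rep_lens, function(L)
    data.frame(start = integer(), end = integer()))

  orfs <- list()       # per-ORF truth rows
  txs <- list()        # transcripts: tx_id, replicon, strand, start, end, abundance
  rnas <- list()       # untranslated RNA features (sRNA/hkRNA)
  write_seq <- function(rid, start, nt) {
    v <- strsplit(nt, "", fixed = TRUE)[[1L]]
    seqs[[rid]][(start + 1L):(start + length(v))] <<- v
  }
  occupy <- function(rid, s, e) {
    occ[[rid]] <<- rbind(occ[[rid]], data.frame(start = s, end = e))
  }
  tx_n <- 0L
  add_tx <- function(rid, strand, s, e, abundance) {
    tx_n <<- tx_n + 1L
    id <- sprintf("tx_%03d", tx_n)
    txs[[id]] <<- data.frame(tx_id = id, replicon_id = rid, strand = strand,
                             start = s, end = e, abundance = abundance)
    id
  }
  orf_row <- function(id, rid, strand, s, e, class, tx_id, te_raw,
                      translated, protein, nt, annotated, context,
                      leaderless = FALSE) {
    data.frame(feature_id = id, replicon_id = rid, strand = strand,
               start = s, end = e, feature_class = class, tx_id = tx_id,
               te_raw = te_raw, translated = translated,
               protein = protein,
               start_codon = substr(nt, 1L, 3L),
               stop_codon = substr(nt, nchar(nt) - 2L, nchar(nt)),
               annotated = annotated, context = context,
               leaderless = leaderless, stringsAsFactors = FALSE)
  }
  # genomic interval of an ORF placed at offset `off` within a transcript
  # written as `tx_nt` at genomic `tx_start` on `strand`
  orf_coords <- function(tx_start, tx_len, strand, off, orf_len) {
    if (strand == "+") c(tx_start + off, tx_start + off + orf_len)
    else c(tx_start + tx_len - off - orf_len, tx_start + tx_len - off)
  }

  plant_mrna <- function(kind, aa_len, utr5, utr3, annotated, id,
                         uorf_aa = NULL, anti_aa = NULL, orf_nt = NULL,
                         leaderless = FALSE) {
    orf_len <- (aa_len + 1L) * 3L
    if (is.null(orf_nt)) orf_nt <- random_orf_nt(aa_len)
    tx_nt <- paste0(random_nt(utr5), orf_nt, random_nt(utr3))
    tx_len <- nchar(tx_nt)
    strand <- sample(c("+", "-"), 1L)
    pos <- place_interval(tx_len, occ, rep_lens)
    rid <- pos$replicon_id; s <- pos$start
    write_seq(rid, s, if (strand == "+") tx_nt else revcomp(tx_nt))
    occupy(rid, s, s + tx_len)
    abund <- stats::rlnorm(1L, log(1), 0.5)
    tx_id <- add_tx(rid, strand, s, s + tx_len, abund)
    te <- draw_te(1L, config)
    oc <- orf_coords(s, tx_len, strand, utr5, orf_len)
    rows <- list(orf_row(id, rid, strand, oc[[1L]], oc[[2L]],
                         if (aa_len <= 70L) "sORF" else "CDS", tx_id, te,
                         TRUE, translate_cds(orf_nt), orf_nt, annotated,
                         if (kind == "sorf") "intergenic" else "cds",
                         leaderless = leaderless))
    if (!is.null(uorf_aa)) {
      # upstream ORF at the very beginning of the 5'-UTR, well clear of the
      # main start so pile-ups do not blur into each other
      u_len <- (uorf_aa + 1L) * 3L
      u_nt <- random_orf_nt(uorf_aa)
      u_off <- 2L
      uc <- orf_coords(s, tx_len, strand, u_off, u_len)
      tx_nt_mod <- paste0(substr(tx_nt, 1L, u_off), u_nt,
                          substr(tx_nt, u_off + u_len + 1L, tx_len))
      write_seq(rid, s, if (strand == "+") tx_nt_mod else revcomp(tx_nt_mod))
      rows <- c(rows, list(orf_row(paste0(id, "_uorf"), rid, strand,
                                   uc[[1L]], uc[[2L]], "sORF", tx_id,
                                   draw_te(1L, config), TRUE,
                                   translate_cds(u_nt), u_nt, FALSE,
                                   "five_prime_UTR")))
    }
    if (!is.null(anti_aa)) {
      # antisense sORF opposite the host 3'-UTR (host CDS is untouched)
      a_len <- (anti_aa + 1L) * 3L
      a_nt <- random_orf_nt(anti_aa)
      a_off <- utr5 + orf_len + 5L            # offset within transcript
      # antisense ORF written on the opposite strand of the transcript
      anti_sense_in_tx <- revcomp(a_nt)       # as it appears in tx orientation
      tx_nt_cur <- paste(seqs[[rid]][(s + 1L):(s + tx_len)], collapse = "")
      if (strand == "-") tx_nt_cur <- revcomp(tx_nt_cur)
      tx_nt_mod <- paste0(substr(tx_nt_cur, 1L, a_off), anti_sense_in_tx,
                          substr(tx_nt_cur, a_off + a_len + 1L, tx_len))
      write_seq(rid, s, if (strand == "+") tx_nt_mod else revcomp(tx_nt_mod))
      ac <- orf_coords(s, tx_len, strand, a_off, a_len)
      a_strand <- if (strand == "+") "-" else "+"
      # give the antisense sORF its own short transcript
      a_pad <- 8L
      at_s <- max(s, ac[[1L]] - a_pad); at_e <- min(s + tx_len, ac[[2L]] + a_pad)
      a_tx <- add_tx(rid, a_strand, at_s, at_e, stats::rlnorm(1L, log(1), 0.5))
      rows <- c(rows, list(orf_row(paste0(id, "_anti"), rid, a_strand,
                                   ac[[1L]], ac[[2L]], "sORF", a_tx,
                                   draw_te(1L, config), TRUE,
                                   translate_cds(a_nt), a_nt, FALSE,
                                   "antisense")))
    }
    rows
  }

  # --- operon: n genes on one transcript, gaps 14 and 12 nt then 30 nt ---
  n_op <- config$n_operon_genes
  if (n_op >= 2L) {
    gaps <- c(14L, 12L, rep(30L, max(0L, n_op - 3L)))[seq_len(n_op - 1L)]
    aa <- sample(60:120, n_op, replace = TRUE)
    nts <- vapply(aa, random_orf_nt, "")
    utr5 <- 25L; utr3 <- 20L
    parts <- character(2L * n_op - 1L)
    parts[seq(1L, by = 2L, length.out = n_op)] <- nts
    if (n_op > 1L)
      parts[seq(2L, by = 2L, length.out = n_op - 1L)] <-
        vapply(gaps, random_nt, "")
    tx_nt <- paste0(random_nt(utr5), paste(parts, collapse = ""),
                    random_nt(utr3))
    tx_len <- nchar(tx_nt)
    strand <- sample(c("+", "-"), 1L)
    pos <- place_interval(tx_len, occ, rep_lens)
    rid <- pos$replicon_id; s <- pos$start
    write_seq(rid, s, if (strand == "+") tx_nt else revcomp(tx_nt))
    occupy(rid, s, s + tx_len)
    tx_id <- add_tx(rid, strand, s, s + tx_len,
                    stats::rlnorm(1L, log(1), 0.5))
    off <- utr5
    for (g in seq_len(n_op)) {
      olen <- (aa[[g]] + 1L) * 3L
      oc <- orf_coords(s, tx_len, strand, off, olen)
      orfs[[length(orfs) + 1L]] <- orf_row(
        sprintf("operon_g%d", g), rid, strand, oc[[1L]], oc[[2L]], "CDS",
        tx_id, draw_te(1L, config), TRUE, translate_cds(nts[[g]]),
        nts[[g]], TRUE, "cds")
      off <- off + olen + if (g < n_op) gaps[[g]] else 0L
    }
  }

  # --- standalone CDS; the first few host uORFs / antisense sORFs ---
  n_cds <- config$n_translated_cds
  for (i in seq_len(n_cds)) {
    aa <- sample(71:350, 1L)
    host_uorf <- i <= config$n_uorfs
    host_anti <- !host_uorf &&
      i <= config$n_uorfs + config$n_antisense_sorfs
    uorf_aa <- if (host_uorf) sample(6:15, 1L) else NULL
    anti_aa <- if (host_anti) sample(12:30, 1L) else NULL
    utr5 <- if (host_uorf) ((uorf_aa + 1L) * 3L) + 62L else sample(10:60, 1L)
    utr3 <- if (host_anti) ((anti_aa + 1L) * 3L) + 20L else sample(5:40, 1L)
    orfs <- c(orfs, plant_mrna("cds", aa, utr5, utr3, TRUE,
                               sprintf("cds_%03d", i),
                               uorf_aa = uorf_aa, anti_aa = anti_aa))
  }

  # --- standalone sORFs (annotated + novel, some leaderless, one dup pair) ---
  n_s <- config$n_translated_sorfs
  n_annot <- round(n_s * config$sorf_annotated_frac)
  dup_nt <- if (config$n_duplicated_sorfs > 0L)
    random_orf_nt(sample(25:50, 1L)) else NULL
  for (i in seq_len(n_s)) {
    aa <- sample(10:70, 1L)
    leaderless <- stats::runif(1L) < config$leaderless_frac
    utr5 <- if (leaderless) 0L else sample(15:50, 1L)
    is_dup <- !is.null(dup_nt) && i > n_s - 2L * config$n_duplicated_sorfs
    nt <- if (is_dup) dup_nt else NULL
    if (is_dup) aa <- nchar(dup_nt) / 3L - 1L
    orfs <- c(orfs, plant_mrna("sorf", aa, utr5, sample(5:30, 1L),
                               i <= n_annot, sprintf("sorf_%03d", i),
                               orf_nt = nt, leaderless = leaderless))
  }

  # --- untranslated sRNAs with a decoy ORF inside; untranslated hkRNAs ---
  for (i in seq_len(config$n_untranslated_srnas)) {
    aa <- sample(10:30, 1L)
    olen <- (aa + 1L) * 3L
    pre <- sample(10:40, 1L); post <- sample(10:40, 1L)
    o_nt <- random_orf_nt(aa)
    nt <- paste0(random_nt(pre), o_nt, random_nt(post))
    strand <- sample(c("+", "-"), 1L)
    pos <- place_interval(nchar(nt), occ, rep_lens)
    rid <- pos$replicon_id; s <- pos$start
    write_seq(rid, s, if (strand == "+") nt else revcomp(nt))
    occupy(rid, s, s + nchar(nt))
    tx_id <- add_tx(rid, strand, s, s + nchar(nt),
                    stats::rlnorm(1L, log(1), 0.5))
    oc <- orf_coords(s, nchar(nt), strand, pre, olen)
    rnas[[length(rnas) + 1L]] <- data.frame(
      feature_id = sprintf("srna_%03d", i), replicon_id = rid,
      strand = strand, start = s, end = s + nchar(nt),
      feature_class = "sRNA", tx_id = tx_id, stringsAsFactors = FALSE)
    orfs[[length(orfs) + 1L]] <- orf_row(
      sprintf("srna_%03d_decoy", i), rid, strand, oc[[1L]], oc[[2L]],
      "sORF", tx_id, 0, FALSE, translate_cds(o_nt), o_nt, FALSE,
      "sRNA_hosted")
  }
  for (i in seq_len(config$n_hkrnas)) {
    len <- sample(80:150, 1L)
    nt <- random_nt(len)
    strand <- sample(c("+", "-"), 1L)
    pos <- place_interval(len, occ, rep_lens)
    rid <- pos$replicon_id; s <- pos$start
    write_seq(rid, s, if (strand == "+") nt else revcomp(nt))
    occupy(rid, s, s + len)
    tx_id <- add_tx(rid, strand, s, s + len, stats::rlnorm(1L, log(3), 0.4))
    rnas[[length(rnas) + 1L]] <- data.frame(
      feature_id = sprintf("hkrna_%03d", i), replicon_id = rid,
      strand = strand, start = s, end = s + len, feature_class = "hkRNA",
      tx_id = tx_id, stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, orfs)
  tx_df <- do.call(rbind, txs)
  rna_df <- if (length(rnas)) do.call(rbind, rnas) else NULL
  rownames(truth) <- rownames(tx_df) <- NULL

  # Planted TE on the RPKM-ratio scale: the raw levels are converted to the
  # exact estimand of the downstream quantifier, using the expected library
  # compositions and the exact per-feature probability that an RNA fragment
  # overlaps the ORF interval within its (possibly short) transcript.
  fl_rna <- mean(config$rna_frag_range)
  fls <- seq(config$rna_frag_range[[1L]], config$rna_frag_range[[2L]])
  abund <- stats::setNames(tx_df$abundance, tx_df$tx_id)
  tx_s <- stats::setNames(tx_df$start, tx_df$tx_id)
  tx_e <- stats::setNames(tx_df$end, tx_df$tx_id)
  tx_len <- tx_e - tx_s
  orf_len <- truth$end - truth$start
  tr <- truth$translated
  ribo_int <- ifelse(tr, truth$te_raw * abund[truth$tx_id] * orf_len, 0)
  rna_int <- abund * pmax(tx_len - fl_rna + 1, 1)
  # mean over fragment lengths of P(fragment start yields >=1 nt overlap)
  p_overlap <- vapply(seq_len(nrow(truth)), function(i) {
    ts <- tx_s[[truth$tx_id[[i]]]]; te_ <- tx_e[[truth$tx_id[[i]]]]
    os <- truth$start[[i]]; oe <- truth$end[[i]]
    mean(vapply(fls, function(fl) {
      S <- max(te_ - ts - fl + 1L, 1L)
      vlo <- max(ts, os - fl + 1L)
      vhi <- min(ts + S - 1L, oe - 1L)
      max(vhi - vlo + 1L, 0L) / S
    }, 0))
  }, 0)
  exp_rna_orf <- (rna_int[truth$tx_id] / abund[truth$tx_id]) * p_overlap
  truth$te <- ifelse(
    tr,
    truth$te_raw * orf_len * sum(rna_int) / (sum(ribo_int) * exp_rna_orf),
    0)

  replicons <- lapply(names(rep_lens), function(rid)
    replicon(rid, paste(seqs[[rid]], collapse = "")))
  names(replicons) <- names(rep_lens)

  # --- truth annotation set: CDS, annotated sORFs, UTRs, RNAs, transcripts ---
  ann_rows <- list()
  a_orfs <- truth[truth$annotated, , drop = FALSE]
  if (nrow(a_orfs)) {
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      feature_id = a_orfs$feature_id, replicon_id = a_orfs$replicon_id,
      strand = a_orfs$strand, start = a_orfs$start, end = a_orfs$end,
      feature_class = a_orfs$feature_class, stringsAsFactors = FALSE)
    # UTRs of annotated monocistronic transcripts
    for (k in seq_len(nrow(a_orfs))) {
      f <- a_orfs[k, ]
      tx <- tx_df[tx_df$tx_id == f$tx_id, ]
      if (sum(truth$tx_id == f$tx_id & truth$annotated) > 1L) next
      up <- if (f$strand == "+") c(tx$start, f$start) else c(f$end, tx$end)
      dn <- if (f$strand == "+") c(f$end, tx$end) else c(tx$start, f$start)
      if (up[[2L]] > up[[1L]])
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          feature_id = paste0(f$feature_id, "_5utr"),
          replicon_id = f$replicon_id, strand = f$strand,
          start = up[[1L]], end = up[[2L]],
          feature_class = "five_prime_UTR", stringsAsFactors = FALSE)
      if (dn[[2L]] > dn[[1L]])
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          feature_id = paste0(f$feature_id, "_3utr"),
          replicon_id = f$replicon_id, strand = f$strand,
          start = dn[[1L]], end = dn[[2L]],
          feature_class = "three_prime_UTR", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(rna_df))
    ann_rows[[length(ann_rows) + 1L]] <- rna_df[, c(
      "feature_id", "replicon_id", "strand", "start", "end",
      "feature_class")]
  # transcript extents (class 'other') for mRNA transcripts
  mrna_tx <- tx_df[tx_df$tx_id %in% truth$tx_id[truth$translated], ]
  ann_rows[[length(ann_rows) + 1L]] <- data.frame(
    feature_id = mrna_tx$tx_id, replicon_id = mrna_tx$replicon_id,
    strand = mrna_tx$strand, start = mrna_tx$start, end = mrna_tx$end,
    feature_class = "other", stringsAsFactors = FALSE)
  ann <- do.call(rbind, ann_rows)
  annotation <- annotation_set(
    "truth", 1L,
    feature_table(ann$feature_id, ann$replicon_id, ann$strand, ann$start,
                  ann$end, ann$feature_class, source = "truth",
                  replicons = replicons))

  # --- candidate table emulating predictor output for novel ORFs ---
  nov <- truth[!truth$annotated &
                 truth$feature_class %in% c("sORF", "CDS"), , drop = FALSE]
  candidates <- data.frame(
    candidate_id = paste0("cand_", nov$feature_id),
    feature_id = nov$feature_id,
    replicon_id = nov$replicon_id, strand = nov$strand,
    start = nov$start, end = nov$end,
    start_codon = nov$start_codon, stop_codon = nov$stop_codon,
    aa_length = (nov$end - nov$start) %/% 3L - 1L,
    deepribo_score = ifelse(nov$translated,
                            stats::runif(nrow(nov), 0.2, 2),
                            stats::runif(nrow(nov), -2, 0.5)),
    reparation_called = nov$translated,
    stringsAsFactors = FALSE)

  structure(list(replicons = replicons, truth = truth,
                 transcripts = tx_df, rnas = rna_df,
                 annotation = annotation, candidates = candidates,
                 config = config),
            class = "sim_genome")
}

#' Simulate aligned Ribo-seq and RNA-seq reads
#'
#' RNA-seq fragments tile whole transcripts uniformly; Ribo-seq footprints
#' are emitted only from translated ORFs, with 5' ends piled up at 16 nt
#' upstream of the start codon, 3' ends at 16 nt downstream of the stop
#' codon, uniform body coverage in between, and read counts Poisson around
#' an expectation proportional to planted TE times transcript abundance.
#' Protection never extends beyond `initiation_pileup_extent` outside the
#' ORF.
#'
#' @param genome A [make_genome()] result.
#' @param config The same [sim_config()] (defaults to the genome's).
#' @return A `data.frame` of aligned reads: `replicon_id`, `strand`,
#'   `start`, `end` (0-based half-open), `library` (RIBO/RNA), `sample_id`.
#' @export
simulate_reads <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  truth <- genome$truth
  tx <- genome$transcripts
  ext <- config$initiation_pileup_extent
  out <- vector("list", 0L)

  abund <- stats::setNames(tx$abundance, tx$tx_id)
  fl_rna_opts <- seq(config$rna_frag_range[[1L]], config$rna_frag_range[[2L]])
  rna_int <- tx$abundance * pmax((tx$end - tx$start) - mean(fl_rna_opts) + 1, 1)
  tr <- truth[truth$translated, , drop = FALSE]
  orf_len <- tr$end - tr$start
  ribo_int <- tr$te_raw * abund[tr$tx_id] * orf_len
  p_init_len <- ifelse(config$footprint_lengths == config$init_boost_length,
                       pmin(config$init_frac * config$init_boost_factor, 0.9),
                       config$init_frac)

  for (r in seq_len(config$n_replicates)) {
    # RNA library
    n_tx <- stats::rpois(nrow(tx),
                         config$library_size * rna_int / sum(rna_int))
    rna_reads <- lapply(which(n_tx > 0L), function(i) {
      n <- n_tx[[i]]
      fl <- sample(fl_rna_opts, n, replace = TRUE)
      span <- pmax((tx$end[[i]] - tx$start[[i]]) - fl + 1L, 1L)
      s <- tx$start[[i]] + floor(stats::runif(n) * span)
      data.frame(replicon_id = tx$replicon_id[[i]], strand = tx$strand[[i]],
                 start = as.integer(s),
                 end = as.integer(pmin(s + fl, tx$end[[i]])),
                 stringsAsFactors = FALSE)
    })
    rna <- do.call(rbind, rna_reads)
    rna$library <- "RNA"; rna$sample_id <- sprintf("rna_%d", r)
    out[[length(out) + 1L]] <- rna

    # RIBO library
    n_orf <- stats::rpois(nrow(tr),
                          config$library_size * ribo_int / sum(ribo_int))
    ribo_reads <- lapply(which(n_orf > 0L), function(i) {
      n <- n_orf[[i]]
      L <- sample(config$footprint_lengths, n, replace = TRUE,
                  prob = config$footprint_weights)
      u <- stats::runif(n)
      p_i <- p_init_len[match(L, config$footprint_lengths)]
      kind <- ifelse(u < p_i, "init",
                     ifelse(u < p_i + config$term_frac, "term", "body"))
      s0 <- tr$start[[i]]; e0 <- tr$end[[i]]; str <- tr$strand[[i]]
      if (str == "+") {
        five <- ifelse(kind == "init", s0 - ext,
                ifelse(kind == "term", e0 + ext - L,
                       s0 - ext +
                         floor(stats::runif(n) * pmax(e0 + ext - L -
                                                        (s0 - ext) + 1L, 1L))))
        st <- five; en <- five + L
      } else {
        # biological 5' end is the genomic right edge
        three_right <- ifelse(kind == "init", e0 + ext,
                       ifelse(kind == "term", s0 - ext + L,
                              s0 - ext + L +
                                floor(stats::runif(n) *
                                        pmax(e0 + ext - (s0 - ext + L) + 1L,
                                             1L))))
        en <- three_right; st <- three_right - L
      }
      data.frame(replicon_id = tr$replicon_id[[i]], strand = str,
                 start = as.integer(st), end = as.integer(en),
                 stringsAsFactors = FALSE)
    })
    ribo <- do.call(rbind, ribo_reads)
    if (config$background_rate > 0) {
      nb <- stats::rpois(1L, config$background_rate)
      if (nb > 0L) {
        rl <- sample(config$footprint_lengths, nb, replace = TRUE,
                     prob = config$footprint_weights)
        rid <- sample(names(genome$replicons), nb, replace = TRUE)
        lens <- vapply(genome$replicons, `[[`, 0L, "length")
        s <- floor(stats::runif(nb) * (lens[rid] - rl))
        ribo <- rbind(ribo, data.frame(replicon_id = rid,
                                       strand = sample(c("+", "-"), nb,
                                                       replace = TRUE),
                                       start = as.integer(s),
                                       end = as.integer(s + rl),
                                       stringsAsFactors = FALSE))
      }
    }
    ribo$library <- "RIBO"; ribo$sample_id <- sprintf("ribo_%d", r)
    out[[length(out) + 1L]] <- ribo
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  # drop the rare read clipped at a replicon edge
  lens <- vapply(genome$replicons, `[[`, 0L, "length")
  reads <- reads[reads$start >= 0L & reads$end <= lens[reads$replicon_id], ]
  reads
}

#' Simulate a filtered PSM table for one protease approach
#'
#' Peptides are sampled from in-silico digests of the expressed (translated)
#' truth proteins; for the no-protease approach random substrings within the
#' configured length bounds are drawn. PSM counts and replicate labels are
#' drawn per peptide.
#'
#' @param genome A [make_genome()] result.
#' @param protease `trypsin`, `lysC` or `none`.
#' @param config A [sim_config()].
#' @param detect_frac Fraction of digest peptides observed.
#' @param nonspecific_len Length bounds for no-protease peptides.
#' @return `data.frame` with `peptide_sequence`, `replicate_id`,
#'   `psm_count`, `sample_condition` and the originating `feature_id`.
#' @export
simulate_psms <- function(genome, protease = c("trypsin", "lysC", "none"),
                          config = genome$config, detect_frac = 0.6,
                          nonspecific_len = c(6L, 25L)) {
  protease <- match.arg(protease)
  set.seed(config$seed + 2L + match(protease,
                                    c("trypsin", "lysC", "none")))
  prot <- genome$truth[genome$truth$translated, c("feature_id", "protein")]
  rows <- list()
  for (k in seq_len(nrow(prot))) {
    p <- prot$protein[[k]]
    if (protease == "none") {
      n <- stats::rpois(1L, 3L)
      if (n == 0L || nchar(p) < nonspecific_len[[1L]]) next
      len <- sample(seq(nonspecific_len[[1L]],
                        min(nonspecific_len[[2L]], nchar(p))), n,
                    replace = TRUE)
      s <- vapply(len, function(l) sample.int(nchar(p) - l + 1L, 1L), 0L)
      peps <- substring(p, s, s + len - 1L)
    } else {
      peps <- digest(p, protease, max_missed = 2L)
      peps <- peps[nchar(peps) >= 5L]
      if (!length(peps)) next
      peps <- peps[stats::runif(length(peps)) < detect_frac]
    }
    if (!length(peps)) next
    for (pep in unique(peps)) {
      reps <- sort(sample.int(config$n_psm_replicates,
                              sample.int(config$n_psm_replicates, 1L)))
      for (rr in reps) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_sequence = pep, replicate_id = sprintf("ms_rep%d", rr),
          psm_count = 1L + stats::rpois(1L, 1.2),
          sample_condition = "minimal_medium",
          feature_id = prot$feature_id[[k]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write simulator outputs to plain-text files
#'
#' @param genome A [make_genome()] result.
#' @param reads Optional read table from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(genome, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation_truth.gff3"),
             truth = file.path(dir, "truth_features.tsv"),
             transcripts = file.path(dir, "truth_transcripts.tsv"),
             candidates = file.path(dir, "candidates.tsv"))
  write_fasta(genome$replicons, paths[["genome"]])
  write_gff(genome$annotation$features, paths[["annotation"]])
  data.table::fwrite(genome$truth, paths[["truth"]], sep = "\t")
  data.table::fwrite(genome$transcripts, paths[["transcripts"]], sep = "\t")
  data.table::fwrite(genome$candidates, paths[["candidates"]], sep = "\t")
  if (!is.null(reads)) {
    paths[["reads"]] <- file.path(dir, "reads.tsv")
    data.table::fwrite(reads, paths[["reads"]], sep = "\t")
  }
  invisible(paths)
}
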