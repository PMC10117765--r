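# Translation-filter cascades for annotated sORFs and novel ORF candidates,
# quantitative proxies for the four visual curation criteria, genomic-context
# classification and summary tables.
#
# Cascade thresholds (inclusive unless noted): mean TE >= 0.5, RNA-seq and
# Ribo-seq RPKM >= 10 (mean across replicates for annotated sORFs; in every
# replicate for novel candidates), and for novel candidates a predictor
# (DeepRibo) score strictly greater than -0.5.

#' Filter thresholds for translation calls
#'
#' @param te_min Minimum mean translation efficiency (inclusive).
#' @param rpkm_min Minimum RPKM for both libraries (inclusive).
#' @param deepribo_min Predictor score bound for novel candidates; the
#'   comparison is strict (`score > deepribo_min`).
#' @param rpkm_rule `mean` (RPKM averaged across replicates) or
#'   `each_replicate` (required in every replicate).
#' @return A list with class `sorf_thresholds`.
#' @export
sorf_thresholds <- function(te_min = 0.5, rpkm_min = 10,
                            deepribo_min = -0.5,
                            rpkm_rule = c("mean", "each_replicate")) {
  rpkm_rule <- match.arg(rpkm_rule)
  stopifnot(te_min >= 0, rpkm_min >= 0)
  structure(list(te_min = te_min, rpkm_min = rpkm_min,
                 deepribo_min = deepribo_min, rpkm_rule = rpkm_rule),
            class = "sorf_thresholds")
}

rpkm_cols <- function(quants, lib) {
  grep(paste0("^rpkm_", lib, "_"), names(quants), value = TRUE)
}

# TE/RPKM cascade shared by both filters; returns logical columns
apply_cascade <- function(q, thresholds, rpkm_rule) {
  ribo <- as.matrix(q[, rpkm_cols(q, "ribo"), drop = FALSE])
  rna <- as.matrix(q[, rpkm_cols(q, "rna"), drop = FALSE])
  pass_te <- !is.na(q$mean_te) & q$mean_te >= thresholds$te_min
  if (rpkm_rule == "mean") {
    pass_rpkm <- rowMeans(ribo) >= thresholds$rpkm_min &
      rowMeans(rna) >= thresholds$rpkm_min
  } else {
    pass_rpkm <- apply(ribo >= thresholds$rpkm_min, 1L, all) &
      apply(rna >= thresholds$rpkm_min, 1L, all)
  }
  data.frame(pass_te = pass_te, pass_rpkm = pass_rpkm)
}

#' Translation filter for annotated sORFs
#'
#' An annotated sORF is called translated when its mean TE and its RNA-seq
#' and Ribo-seq RPKM meet the thresholds; boundary values pass (the
#' comparisons are inclusive). Undefined mean TE fails with the reason
#' recorded.
#'
#' @param quants [quantify_features()] rows for the sORFs.
#' @param thresholds A [sorf_thresholds()]; its `rpkm_rule` applies
#'   (default `mean`).
#' @return `data.frame` of translation calls: `feature_id`, `pass_te`,
#'   `pass_rpkm`, `verdict` (`filtered_pass`/`fail`), `reason`.
#' @export
filter_annotated_sorfs <- function(quants, thresholds = sorf_thresholds()) {
  cc <- apply_cascade(quants, thresholds, thresholds$rpkm_rule)
  verdict <- ifelse(cc$pass_te & cc$pass_rpkm, "filtered_pass", "fail")
  reason <- ifelse(is.na(quants$mean_te), "undefined_te",
                   ifelse(!cc$pass_te, "low_te",
                          ifelse(!cc$pass_rpkm, "low_rpkm", "")))
  data.frame(feature_id = quants$feature_id, pass_te = cc$pass_te,
             pass_rpkm = cc$pass_rpkm, verdict = verdict, reason = reason,
             stringsAsFactors = FALSE)
}

#' Translation filter for novel ORF candidates
#'
#' Novel candidates must additionally carry a predictor score strictly
#' greater than `deepribo_min`, and the RPKM rule is applied in every
#' replicate.
#'
#' @param quants [quantify_features()] rows for the candidates (feature_id
#'   = candidate_id).
#' @param candidates Candidate table with `candidate_id` and
#'   `deepribo_score`.
#' @param thresholds A [sorf_thresholds()].
#' @return `data.frame` of translation calls with `pass_score`.
#' @export
filter_novel_candidates <- function(quants, candidates,
                                    thresholds = sorf_thresholds()) {
  idx <- match(quants$feature_id, candidates$candidate_id)
  if (anyNA(idx)) stop("quant rows without matching candidate")
  score <- candidates$deepribo_score[idx]
  cc <- apply_cascade(quants, thresholds, "each_replicate")
  pass_score <- !is.na(score) & score > thresholds$deepribo_min
  verdict <- ifelse(cc$pass_te & cc$pass_rpkm & pass_score,
                    "filtered_pass", "fail")
  reason <- ifelse(is.na(score), "missing_score",
            ifelse(is.na(quants$mean_te), "undefined_te",
            ifelse(!cc$pass_te, "low_te",
            ifelse(!cc$pass_rpkm, "low_rpkm",
            ifelse(!pass_score, "low_score", "")))))
  data.frame(feature_id = quants$feature_id, pass_te = cc$pass_te,
             pass_rpkm = cc$pass_rpkm, pass_score = pass_score,
             verdict = verdict, reason = reason, stringsAsFactors = FALSE)
}

#' Curation-heuristic parameters
#'
#' Quantitative proxies for the four visual curation criteria: coverage
#' within ORF boundaries (with the ~16 nt initiation/termination
#' protection), exclusion of coverage from residual UTR flanks, evenness of
#' the coverage shape, and a Ribo-seq/RNA-seq signal ratio.
#'
#' @param pileup_extent Protection beyond start/stop codons (nt).
#' @param flank Residual-UTR flank width inspected beyond the protected
#'   window (nt).
#' @param boundary_min Minimum fraction of locus Ribo signal inside the
#'   protected window.
#' @param utr_max Maximum flank/in-ORF Ribo density ratio.
#' @param max_pos_share Maximum share of in-ORF signal at a single
#'   position.
#' @param cv_max Maximum per-codon coefficient of variation.
#' @param ratio_min Minimum in-ORF Ribo/RNA mean-density ratio.
#' @export
curation_params <- function(pileup_extent = 16L, flank = 30L,
                            boundary_min = 0.8, utr_max = 0.3,
                            max_pos_share = 0.5, cv_max = 2.0,
                            ratio_min = 1.0) {
  structure(as.list(environment()), class = "curation_params")
}

#' Quantitative curation flags for one ORF candidate
#'
#' Both tracks should be min-normalized global-mode tracks (the convention
#' used for visual curation in a genome browser). Zero in-ORF Ribo coverage
#' sets every flag to `FALSE`.
#'
#' @param candidate One-row feature/candidate table (`replicon_id`,
#'   `strand`, `start`, `end`).
#' @param ribo_track,rna_track Min-normalized global `coverage_track`s.
#' @param params A [curation_params()].
#' @return List with logical flags `boundary`, `utr_exclusion`, `evenness`,
#'   `signal_ratio`, their numeric sub-scores, and `all_pass`.
#' @export
curation_flags <- function(candidate, ribo_track, rna_track,
                           params = curation_params()) {
  ext <- params$pileup_extent; fl <- params$flank
  rid <- candidate$replicon_id[[1L]]; str <- candidate$strand[[1L]]
  s <- candidate$start[[1L]]; e <- candidate$end[[1L]]
  win <- track_slice(ribo_track, rid, str, s - ext, e + ext)
  locus <- track_slice(ribo_track, rid, str, s - ext - fl, e + ext + fl)
  orf_ribo <- track_slice(ribo_track, rid, str, s, e)
  orf_rna <- track_slice(rna_track, rid, str, s, e)
  flanks <- c(track_slice(ribo_track, rid, str, s - ext - fl, s - ext),
              track_slice(ribo_track, rid, str, e + ext, e + ext + fl))
  if (sum(orf_ribo) == 0) {
    return(list(boundary = FALSE, utr_exclusion = FALSE, evenness = FALSE,
                signal_ratio = FALSE, all_pass = FALSE,
                scores = list(boundary_frac = 0, flank_ratio = NA_real_,
                              max_pos_share = NA_real_,
                              codon_cv = NA_real_, ribo_rna_ratio = 0)))
  }
  boundary_frac <- if (sum(locus) > 0) sum(win) / sum(locus) else 0
  in_density <- mean(orf_ribo)
  flank_ratio <- mean(flanks) / in_density
  pos_share <- max(orf_ribo) / sum(orf_ribo)
  codon_sums <- colSums(matrix(orf_ribo, nrow = 3L))
  codon_cv <- if (mean(codon_sums) > 0)
    stats::sd(codon_sums) / mean(codon_sums) else Inf
  ratio <- if (mean(orf_rna) > 0) in_density / mean(orf_rna) else Inf
  flags <- list(
    boundary = boundary_frac >= params$boundary_min,
    utr_exclusion = flank_ratio <= params$utr_max,
    evenness = pos_share <= params$max_pos_share & codon_cv <= params$cv_max,
    signal_ratio = ratio >= params$ratio_min)
  flags$all_pass <- all(unlist(flags))
  flags$scores <- list(boundary_frac = boundary_frac,
                       flank_ratio = flank_ratio, max_pos_share = pos_share,
                       codon_cv = codon_cv, ribo_rna_ratio = ratio)
  flags
}

#' Full sORF call: filter cascade plus curation
#'
#' Verdicts: `translated_high_confidence` when the cascade and all four
#' curation flags pass; `filtered_pass` when only the cascade passes;
#' `fail` otherwise.
#'
#' @param quants Quantification rows for the candidates.
#' @param candidates Candidate table (feature rows plus `deepribo_score`;
#'   `candidate_id` used as feature id).
#' @param ribo_track,rna_track Min-normalized global tracks for curation.
#' @param thresholds A [sorf_thresholds()].
#' @param params A [curation_params()].
#' @return Calls `data.frame` with flag columns, sub-scores and `verdict`.
#' @export
call_sorfs <- function(quants, candidates, ribo_track, rna_track,
                       thresholds = sorf_thresholds(),
                       params = curation_params()) {
  calls <- filter_novel_candidates(quants, candidates, thresholds)
  idx <- match(calls$feature_id, candidates$candidate_id)
  flag_rows <- lapply(idx, function(i)
    curation_flags(candidates[i, ], ribo_track, rna_track, params))
  for (nm in c("boundary", "utr_exclusion", "evenness", "signal_ratio"))
    calls[[paste0("flag_", nm)]] <- vapply(flag_rows, `[[`, TRUE, nm)
  for (nm in c("boundary_frac", "flank_ratio", "max_pos_share", "codon_cv",
               "ribo_rna_ratio"))
    calls[[nm]] <- vapply(flag_rows, function(x) x$scores[[nm]], 0)
  all_flags <- vapply(flag_rows, `[[`, TRUE, "all_pass")
  calls$verdict <- ifelse(calls$verdict == "filtered_pass" & all_flags,
                          "translated_high_confidence", calls$verdict)
  calls
}

#' Resolve nested/overlapping candidates sharing a stop codon
#'
#' Among candidates with the same (replicon, strand, stop), the one with
#' the highest predictor score is kept (ties broken toward the longest);
#' the rest are returned flagged as shadowed.
#'
#' @param candidates Candidate table.
#' @return The table with a logical `shadowed` column.
#' @export
resolve_shadowed <- function(candidates) {
  stop_coord <- ifelse(candidates$strand == "+", candidates$end,
                       candidates$start)
  key <- paste(candidates$replicon_id, candidates$strand, stop_coord)
  len <- candidates$end - candidates$start
  score <- candidates$deepribo_score
  keep <- unlist(lapply(split(seq_along(key), key), function(ii) {
    o <- ii[order(-score[ii], -len[ii])]
    o[[1L]]
  }))
  candidates$shadowed <- !seq_len(nrow(candidates)) %in% keep
  candidates
}

#' Genomic-context classification of an sORF
#'
#' Precedence: same-strand containment in a 5'-UTR, then a 3'-UTR, then an
#' sRNA; then operon-internal (contained in a same-strand multi-gene
#' transcript); then antisense (>= 1 nt opposite-strand overlap with any
#' transcript or gene); otherwise intergenic.
#'
#' @param sorf One-row feature table.
#' @param annotation Feature table providing UTRs (`five_prime_UTR`,
#'   `three_prime_UTR`), `sRNA`, `CDS` and transcript extents (class
#'   `other`).
#' @return One of `five_prime_UTR`, `three_prime_UTR`, `sRNA_hosted`,
#'   `operon_internal`, `antisense`, `intergenic`.
#' @export
classify_context <- function(sorf, annotation) {
  same_rep <- annotation$replicon_id == sorf$replicon_id[[1L]]
  ann <- annotation[same_rep, , drop = FALSE]
  s <- sorf$start[[1L]]; e <- sorf$end[[1L]]; str <- sorf$strand[[1L]]
  contains <- ann$start <= s & ann$end >= e & ann$strand == str
  overlaps_anti <- ann$start < e & ann$end > s & ann$strand != str
  if (any(contains & ann$feature_class == "five_prime_UTR"))
    return("five_prime_UTR")
  if (any(contains & ann$feature_class == "three_prime_UTR"))
    return("three_prime_UTR")
  if (any(contains & ann$feature_class == "sRNA"))
    return("sRNA_hosted")
  tx <- ann[ann$feature_class == "other", , drop = FALSE]
  if (nrow(tx) > 0L) {
    hosts <- tx[tx$start <= s & tx$end >= e & tx$strand == str, ,
                drop = FALSE]
    cds <- ann[ann$feature_class == "CDS", , drop = FALSE]
    for (k in seq_len(nrow(hosts))) {
      n_cds <- sum(cds$strand == str & cds$start >= hosts$start[[k]] &
                     cds$end <= hosts$end[[k]])
      if (n_cds >= 2L) return("operon_internal")
    }
  }
  if (any(overlaps_anti & ann$feature_class %in% c("CDS", "sORF", "other",
                                                   "sRNA", "hkRNA")))
    return("antisense")
  "intergenic"
}

#' Summary tables for a set of sORF calls
#'
#' @param candidates Candidate/feature table with `start_codon`,
#'   `stop_codon`, `replicon_id`, `aa_length`.
#' @param length_breaks Histogram bin edges for protein length (aa).
#' @return List of `data.frame`s: `start_codons`, `stop_codons`,
#'   `replicons` (with percentages), `length_histogram`.
#' @export
summarize_sorfs <- function(candidates,
                            length_breaks = seq(0L, 80L, by = 10L)) {
  tab <- function(x) {
    t <- table(x)
    data.frame(value = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  }
  reps <- tab(candidates$replicon_id)
  reps$percent <- 100 * reps$count / sum(reps$count)
  x <- pmin(candidates$aa_length, max(length_breaks))
  bins <- cut(x, breaks = length_breaks, right = TRUE,
              include.lowest = TRUE)
  counts <- as.integer(table(bins))
  list(start_codons = tab(candidates$start_codon),
       stop_codons = tab(candidates$stop_codon),
       replicons = reps,
       length_histogram = data.frame(
         bin_low = length_breaks[-length(length_breaks)],
         bin_high = length_breaks[-1L],
         count = counts))
}
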