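# Per-feature read counts, RPKM and translation efficiency.
#
# Counting rule: a read counts toward a feature when it overlaps the
# feature interval by at least 1 nt on the same strand; a read may count
# toward several overlapping features (permissive, featureCounts-style).
# RPKM = count * 1e9 / (feature_length_nt * total_mapped_reads).
# TE (translation efficiency) per replicate = Ribo RPKM / RNA RPKM, defined
# only when the RNA RPKM is positive; mean TE averages the defined
# replicate values.

#' Count same-strand overlapping reads per feature
#'
#' @param features Feature table.
#' @param reads Read table (one sample).
#' @return Integer vector of counts, one per feature row.
#' @export
count_reads <- function(features, reads) {
  if (nrow(reads) == 0L) return(integer(nrow(features)))
  fg <- features_to_granges(features)
  rg <- GenomicRanges::GRanges(
    seqnames = reads$replicon_id,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand)
  GenomicRanges::countOverlaps(fg, rg, minoverlap = 1L,
                               ignore.strand = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s).
#' @param feature_length_nt Feature length(s) in nt (> 0).
#' @param total_mapped_reads Library total (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length_nt, total_mapped_reads) {
  if (any(feature_length_nt <= 0)) stop("feature length must be positive")
  if (any(total_mapped_reads <= 0)) stop("library total must be positive")
  count * 1e9 / (feature_length_nt * total_mapped_reads)
}

#' Quantify features over paired Ribo-seq/RNA-seq replicates
#'
#' Replicates are paired explicitly through `pairing`, never inferred from
#' sample names.
#'
#' @param features Feature table.
#' @param reads Read table with `library` (RIBO/RNA) and `sample_id`.
#' @param pairing `data.frame` with columns `replicate`, `ribo_sample`,
#'   `rna_sample`.
#' @return A `data.frame` with one row per feature: per-replicate counts,
#'   RPKMs and TE (columns suffixed `_1`, `_2`, ...), and `mean_te` (`NA`
#'   when no replicate TE is defined).
#' @export
quantify_features <- function(features, reads, pairing) {
  stopifnot(all(c("replicate", "ribo_sample", "rna_sample") %in%
                  names(pairing)))
  totals <- table(reads$sample_id)
  out <- features[, c("feature_id", "replicon_id", "strand", "start",
                      "end", "feature_class")]
  len <- features$end - features$start
  te_mat <- matrix(NA_real_, nrow(features), nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    r <- pairing$replicate[[i]]
    ribo_id <- pairing$ribo_sample[[i]]
    rna_id <- pairing$rna_sample[[i]]
    for (s in c(ribo_id, rna_id))
      if (!s %in% names(totals)) stop("no reads for sample '", s, "'")
    cr <- count_reads(features, reads[reads$sample_id == ribo_id, ])
    cn <- count_reads(features, reads[reads$sample_id == rna_id, ])
    rr <- rpkm(cr, len, as.integer(totals[[ribo_id]]))
    rn <- rpkm(cn, len, as.integer(totals[[rna_id]]))
    te <- ifelse(rn > 0, rr / rn, NA_real_)
    te_mat[, i] <- te
    out[[paste0("count_ribo_", r)]] <- cr
    out[[paste0("count_rna_", r)]] <- cn
    out[[paste0("rpkm_ribo_", r)]] <- rr
    out[[paste0("rpkm_rna_", r)]] <- rn
    out[[paste0("te_", r)]] <- te
  }
  out$mean_te <- rowMeans(te_mat, na.rm = TRUE)
  out$mean_te[!is.finite(out$mean_te)] <- NA_real_
  out
}

#' Per-replicate translation efficiency and its mean
#'
#' @param rpkm_ribo,rpkm_rna Numeric vectors of per-replicate RPKMs.
#' @return List with `te` (per replicate, `NA` where the RNA RPKM is zero)
#'   and `mean_te` (`NA` when no replicate is defined).
#' @export
translation_efficiency <- function(rpkm_ribo, rpkm_rna) {
  stopifnot(length(rpkm_ribo) == length(rpkm_rna))
  te <- ifelse(rpkm_rna > 0, rpkm_ribo / rpkm_rna, NA_real_)
  m <- mean(te, na.rm = TRUE)
  list(te = te, mean_te = if (is.finite(m)) m else NA_real_)
}

#' Mean translation efficiency per feature class
#'
#' Features with undefined mean TE are excluded (their number is reported);
#' classes without any defined value are absent from the output rather than
#' zero.
#'
#' @param quants Output of [quantify_features()].
#' @return `data.frame` with `feature_class`, `mean_te`, `n_features`,
#'   `n_excluded`.
#' @export
class_te_summary <- function(quants) {
  out <- lapply(split(quants, quants$feature_class), function(q) {
    ok <- !is.na(q$mean_te)
    if (!any(ok)) return(NULL)
    data.frame(feature_class = q$feature_class[[1L]],
               mean_te = mean(q$mean_te[ok]),
               n_features = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

#' Write a quantification table to TSV
#' @param quants Output of [quantify_features()].
#' @param path Output path.
#' @export
write_quant_table <- function(quants, path) {
  data.table::fwrite(quants, path, sep = "\t")
  invisible(path)
}
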