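# Metagene diagnostics around annotated start codons.
#
# Profile coordinates: position 0 is the first nucleotide of the start
# codon (the biological "+1"); negative positions are upstream. With 5'-end
# single-nucleotide mapping, initiating ribosomes produce a density peak at
# -16; with 3'-end mapping the corresponding peak sits at -16 + L - 1 for
# footprints of length L (+13 for the 30 nt mode).

#' Metagene profile of ribosome density around start codons
#'
#' Each gene's window row is normalized to sum 1 before averaging, so
#' highly expressed genes do not dominate; genes whose window leaves the
#' replicon, and genes with zero window signal, are dropped and counted.
#'
#' @param track A single-nucleotide `coverage_track` (`five_prime` or
#'   `three_prime` mode).
#' @param starts Feature table of CDS whose start codons anchor the
#'   profile.
#' @param window Integer pair `c(upstream, downstream)` around position 0;
#'   must contain 0.
#' @return A `metagene_profile`: list with `positions`, `mean_profile`,
#'   `matrix` (genes x positions, normalized), `n_genes`, `n_dropped`,
#'   `mapping_end`.
#' @export
metagene_profile <- function(track, starts, window = c(-30L, 30L)) {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$mode %in% c("five_prime", "three_prime"))
    stop("metagene profiles require a single-nucleotide track ",
         "(five_prime or three_prime mode)")
  if (window[[1L]] > 0L || window[[2L]] < 0L)
    stop("window must contain position 0")
  if (nrow(starts) == 0L) stop("empty gene set")
  offs <- seq.int(window[[1L]], window[[2L]])
  lens <- vapply(track$data, function(x) length(x[["+"]]), 0L)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(starts))) {
    f <- starts[i, ]
    L <- lens[[f$replicon_id]]
    if (f$strand == "+") {
      pos <- f$start + offs
    } else {
      pos <- (f$end - 1L) - offs
    }
    if (any(pos < 0L | pos >= L)) { dropped <- dropped + 1L; next }
    v <- track$data[[f$replicon_id]][[f$strand]][pos + 1L]
    s <- sum(v)
    if (s == 0) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- v / s
  }
  if (!length(rows))
    stop("no gene contributed signal to the metagene window")
  m <- do.call(rbind, rows)
  colnames(m) <- offs
  structure(list(positions = offs, mean_profile = colMeans(m),
                 matrix = m, n_genes = nrow(m), n_dropped = dropped,
                 mapping_end = track$mode),
            class = "metagene_profile")
}

#' Start-codon enrichment stratified by footprint length
#'
#' For each footprint length, the score is the mean per-position 5'-end
#' density inside the initiation window `[-16, 0]` divided by the mean
#' per-position density over the ORF body (positions downstream of the
#' window, within the gene). A declared proxy for "initiation enrichment";
#' empty length buckets are absent from the result.
#'
#' @param reads Ribo-seq read table (one sample or pooled).
#' @param starts Feature table of CDS.
#' @param replicons Replicon list or named length vector.
#' @param lengths Footprint lengths to stratify over.
#' @param init_window Window `c(from, to)` relative to the start codon.
#' @return `data.frame` with `length`, `enrichment`, `n_reads`.
#' @export
length_stratified_enrichment <- function(reads, starts, replicons,
                                         lengths = 27:33,
                                         init_window = c(-16L, 0L)) {
  rl <- reads$end - reads$start
  reads$sample_id <- "pooled"   # pooled across samples for the diagnostic
  out <- list()
  for (L in lengths) {
    sub <- reads[rl == L, , drop = FALSE]
    if (nrow(sub) == 0L) next
    track <- build_coverage(sub, replicons, mode = "five_prime")
    init_sum <- 0; init_n <- 0L; body_sum <- 0; body_n <- 0L
    for (i in seq_len(nrow(starts))) {
      f <- starts[i, ]
      glen <- f$end - f$start
      iw <- track_slice_rel(track, f, init_window[[1L]], init_window[[2L]])
      bw <- track_slice_rel(track, f, init_window[[2L]] + 1L, glen - 1L)
      init_sum <- init_sum + sum(iw); init_n <- init_n + length(iw)
      body_sum <- body_sum + sum(bw); body_n <- body_n + length(bw)
    }
    enr <- if (body_sum > 0) (init_sum / init_n) / (body_sum / body_n)
           else NA_real_
    out[[length(out) + 1L]] <- data.frame(length = L, enrichment = enr,
                                          n_reads = nrow(sub))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# slice relative to a gene's start codon (position 0), strand-aware
track_slice_rel <- function(track, f, from, to) {
  if (f$strand == "+") {
    track_slice(track, f$replicon_id, "+", f$start + from, f$start + to + 1L)
  } else {
    anchor <- f$end - 1L
    rev(track_slice(track, f$replicon_id, "-", anchor - to, anchor - from + 1L))
  }
}

#' Write a metagene profile as TSV
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @export
write_metagene <- function(profile, path) {
  data.table::fwrite(
    data.frame(position = profile$positions,
               mean_density = profile$mean_profile,
               n_genes = profile$n_genes),
    path, sep = "\t")
  invisible(path)
}
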