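# Strand-aware coverage tracks and their normalizations.
#
# Mapping modes:
#   global     — +1 at every position covered by the read (full read)
#   centered   — +1 at every position after trimming k nt from both read
#                ends; reads shorter than 2k+1 contribute their midpoint
#   five_prime — +1 at the biological 5' end only
#   three_prime— +1 at the biological 3' end only
# Normalizations: mil (per million mapped reads) and min (scaled by the
# smallest mapped-read total among the samples being compared).

#' Build a strand-aware coverage track from aligned reads
#'
#' @param reads Read table (`replicon_id`, `strand`, `start`, `end`,
#'   optionally `library`, `sample_id`); must come from a single sample and
#'   library.
#' @param replicons Named replicon list (or named integer vector of
#'   lengths).
#' @param mode One of `global`, `centered`, `five_prime`, `three_prime`.
#' @param k Trim width for `centered` mode (nt from each end).
#' @return A `coverage_track`: list with `sample_id`, `library`, `mode`,
#'   `normalization` (`raw`), `total_mapped_reads`, and `data` — a list
#'   `data[[replicon]][[strand]]` of per-position numeric vectors.
#' @export
build_coverage <- function(reads, replicons,
                           mode = c("global", "centered", "five_prime",
                                    "three_prime"),
                           k = 5L) {
  mode <- match.arg(mode)
  lens <- replicon_lengths(replicons)
  if ("sample_id" %in% names(reads) &&
      length(unique(reads$sample_id)) > 1L)
    stop("reads from multiple samples; build one track per sample")
  if ("library" %in% names(reads) && length(unique(reads$library)) > 1L)
    stop("reads from multiple libraries; build one track per library")
  if (any(!reads$replicon_id %in% names(lens)))
    stop("read(s) on unknown replicon")
  if (any(reads$start < 0L | reads$end > lens[reads$replicon_id]))
    stop("read(s) outside replicon bounds")

  data <- lapply(lens, function(L)
    list("+" = numeric(L), "-" = numeric(L)))
  for (rid in unique(reads$replicon_id)) {
    for (str in c("+", "-")) {
      rr <- reads[reads$replicon_id == rid & reads$strand == str, ,
                  drop = FALSE]
      if (nrow(rr) == 0L) next
      L <- lens[[rid]]
      v <- numeric(L)
      if (mode == "five_prime") {
        pos <- if (str == "+") rr$start else rr$end - 1L
        tb <- tabulate(pos + 1L, nbins = L)
        v <- as.numeric(tb)
      } else if (mode == "three_prime") {
        pos <- if (str == "+") rr$end - 1L else rr$start
        v <- as.numeric(tabulate(pos + 1L, nbins = L))
      } else {
        s <- rr$start; e <- rr$end
        if (mode == "centered") {
          len <- e - s
          short <- len < 2L * k + 1L
          mid <- s + (len - 1L) %/% 2L
          s2 <- ifelse(short, mid, s + k)
          e2 <- ifelse(short, mid + 1L, e - k)
          s <- s2; e <- e2
        }
        # difference-array accumulation of interval coverage
        ts <- tabulate(s + 1L, nbins = L + 1L)
        te <- tabulate(e + 1L, nbins = L + 1L)
        v <- as.numeric(cumsum(ts - te)[seq_len(L)])
      }
      data[[rid]][[str]] <- v
    }
  }
  structure(list(
    sample_id = if ("sample_id" %in% names(reads) && nrow(reads))
      reads$sample_id[[1L]] else NA_character_,
    library = if ("library" %in% names(reads) && nrow(reads))
      reads$library[[1L]] else NA_character_,
    mode = mode, k = if (mode == "centered") k else NA_integer_,
    normalization = "raw",
    total_mapped_reads = nrow(reads),
    data = data), class = "coverage_track")
}

replicon_lengths <- function(replicons) {
  if (is.numeric(replicons)) {
    stopifnot(!is.null(names(replicons)))
    return(vapply(replicons, as.integer, 0L))
  }
  vapply(replicons, `[[`, 0L, "length")
}

scale_track <- function(track, factor, label) {
  track$data <- lapply(track$data, function(st) lapply(st, `*`, factor))
  track$normalization <- label
  track
}

#' Per-million ("mil") normalization of a raw coverage track
#'
#' Every value is divided by the track's total mapped reads and scaled by
#' one million.
#'
#' @param track A raw `coverage_track`.
#' @return The normalized track (`normalization = "mil"`).
#' @export
normalize_mil <- function(track) {
  stopifnot(inherits(track, "coverage_track"),
            track$normalization == "raw")
  if (track$total_mapped_reads == 0L)
    stop("cannot normalize a track with zero mapped reads")
  scale_track(track, 1e6 / track$total_mapped_reads, "mil")
}

#' Minimum-library ("min") normalization across samples
#'
#' Each track is divided by its own mapped-read total and scaled by the
#' smallest total among all supplied tracks, so the shallowest sample is
#' returned unchanged and all samples become directly comparable.
#'
#' @param tracks A list of raw `coverage_track`s.
#' @return A list of normalized tracks (`normalization = "min"`).
#' @export
normalize_min <- function(tracks) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "coverage_track")))
  totals <- vapply(tracks, `[[`, 0L, "total_mapped_reads")
  if (any(totals == 0L))
    stop("cannot min-normalize: a track has zero mapped reads")
  if (any(vapply(tracks, `[[`, "", "normalization") != "raw"))
    stop("min normalization expects raw tracks")
  m <- min(totals)
  lapply(tracks, function(t)
    scale_track(t, m / t$total_mapped_reads, "min"))
}

#' Extract a stranded slice of a coverage track
#'
#' @param track A `coverage_track`.
#' @param replicon_id,strand,start,end Interval (0-based half-open).
#' @return Numeric vector of length `end - start`, in genomic orientation.
#' @export
track_slice <- function(track, replicon_id, strand, start, end) {
  v <- track$data[[replicon_id]][[strand]]
  if (is.null(v)) stop("unknown replicon '", replicon_id, "'")
  L <- length(v)
  idx <- seq.int(start, end - 1L)
  out <- numeric(length(idx))
  keep <- idx >= 0L & idx < L
  out[keep] <- v[idx[keep] + 1L]
  out
}

#' Write a coverage track as bedGraph (one file per strand)
#'
#' Intervals are 0-based half-open; zero runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param prefix Output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written, plus a JSON metadata sidecar.
#' @return Invisibly, the written paths.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"),
             meta = paste0(prefix, ".meta.json"))
  for (str in c("+", "-")) {
    p <- paths[[if (str == "+") "plus" else "minus"]]
    rows <- list()
    for (rid in names(track$data)) {
      v <- track$data[[rid]][[str]]
      r <- rle(v)
      e <- cumsum(r$lengths)
      s <- e - r$lengths
      keep <- r$values != 0
      if (any(keep))
        rows[[rid]] <- data.frame(chrom = rid, start = s[keep],
                                  end = e[keep], value = r$values[keep])
    }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(chrom = character(), start = integer(),
                          end = integer(), value = numeric())
    data.table::fwrite(df, p, sep = "\t", col.names = FALSE)
  }
  jsonlite::write_json(
    list(sample_id = track$sample_id, library = track$library,
         mode = track$mode, normalization = track$normalization,
         total_mapped_reads = track$total_mapped_reads),
    paths[["meta"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Read aligned reads from the simulator's TSV format
#'
#' Columns: `replicon_id`, `strand`, `start`, `end`, `library`,
#' `sample_id`.
#'
#' @param path TSV path.
#' @return Read table `data.frame`.
#' @export
read_reads_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Read aligned reads from a SAM/BAM file
#'
#' Uses the standard alignment fields; unmapped, secondary and
#' supplementary alignments are dropped (multi-mapper removal is assumed to
#' have happened upstream) and the number of dropped records is reported via
#' a message.
#'
#' @param path SAM or BAM file.
#' @param library,sample_id Labels attached to every read.
#' @return Read table `data.frame` in the internal convention.
#' @export
read_reads_bam <- function(path, library = "RIBO", sample_id = "sample") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  bf <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bf <- Rsamtools::asBam(path, overwrite = TRUE,
                           destination = tempfile())
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "qwidth"), flag = flags)
  b <- Rsamtools::scanBam(bf, param = prm)[[1L]]
  n_all <- Rsamtools::countBam(bf)$records
  if (n_all > length(b$pos))
    message(n_all - length(b$pos),
            " unmapped/secondary/supplementary records dropped")
  data.frame(replicon_id = as.character(b$rname),
             strand = as.character(b$strand),
             start = b$pos - 1L, end = b$pos - 1L + b$qwidth,
             library = library, sample_id = sample_id,
             stringsAsFactors = FALSE)
}
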