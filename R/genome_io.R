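# Genome sequence and annotation I/O.
#
# Internal coordinate convention, used by every module: 0-based, half-open
# [start, end) on the forward strand of the replicon. GFF3 files (1-based,
# inclusive) are converted at the I/O boundary and nowhere else. The stop
# codon is part of a CDS/sORF interval but excluded from aa_length.

FEATURE_CLASSES <- c("CDS", "sORF", "five_prime_UTR", "three_prime_UTR",
                     "sRNA", "hkRNA", "other")

#' Read a genome FASTA file into a set of replicons
#'
#' Sequences are uppercased and RNA (`U`) is converted to DNA (`T`).
#' Non-IUPAC characters, duplicate record ids and empty files are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named list of replicons; each element is a list with fields
#'   `id`, `sequence` (character), `length` (nt) and `circular` (always
#'   `FALSE` on read; origin-wrapping features are not supported).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  reps <- lapply(seq_along(ids), function(i) {
    replicon(ids[[i]], seqs[[i]])
  })
  names(reps) <- ids
  reps
}

#' Construct a replicon
#'
#' @param id Replicon identifier, unique within a genome.
#' @param sequence Nucleotide string (A/C/G/T/N and IUPAC ambiguity codes).
#' @param circular Logical; circular topology is recorded but features
#'   wrapping the origin are rejected throughout.
#' @return A list with class `replicon`.
#' @export
replicon <- function(id, sequence, circular = FALSE) {
  structure(list(id = id, sequence = sequence,
                 length = nchar(sequence), circular = circular),
            class = "replicon")
}

#' Write replicons to a FASTA file
#'
#' @param replicons Named list as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(replicons, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(vapply(replicons, `[[`, "", "sequence"))
  names(ss) <- vapply(replicons, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Build a feature table (collection of FeatureRecords)
#'
#' A feature table is a `data.frame` with one row per feature and columns
#' `feature_id`, `replicon_id`, `strand` (+/-), `start`, `end` (0-based,
#' half-open), `feature_class`, `source` and `aa_length` (`NA` except for
#' CDS/sORF, where the stop codon is inside `[start, end)` but not counted).
#'
#' @param feature_id,replicon_id,strand,start,end,feature_class,source
#'   Vectors, recycled to a common length.
#' @param aa_length Optional; derived from the interval for CDS/sORF rows
#'   when missing.
#' @param replicons Optional named replicon list; when given, intervals are
#'   validated against replicon bounds.
#' @return A `data.frame` feature table.
#' @export
feature_table <- function(feature_id, replicon_id, strand, start, end,
                          feature_class, source = "user", aa_length = NULL,
                          replicons = NULL) {
  ft <- data.frame(feature_id = as.character(feature_id),
                   replicon_id = as.character(replicon_id),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   feature_class = as.character(feature_class),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (!all(ft$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(ft$feature_class %in% FEATURE_CLASSES))
    stop("unknown feature_class: ",
         paste(setdiff(ft$feature_class, FEATURE_CLASSES), collapse = ", "))
  if (any(ft$end <= ft$start)) stop("end must exceed start")
  coding <- ft$feature_class %in% c("CDS", "sORF")
  if (is.null(aa_length)) {
    ft$aa_length <- ifelse(coding, (ft$end - ft$start) %/% 3L - 1L, NA_integer_)
  } else {
    ft$aa_length <- as.integer(aa_length)
  }
  if (any(coding & (ft$end - ft$start) %% 3L != 0L))
    stop("CDS/sORF intervals must have length divisible by 3")
  if (!is.null(replicons)) validate_features(ft, replicons)
  ft
}

validate_features <- function(features, replicons) {
  lens <- vapply(replicons, `[[`, 0L, "length")
  unknown <- setdiff(features$replicon_id, names(lens))
  if (length(unknown))
    stop("features reference unknown replicon(s): ",
         paste(unknown, collapse = ", "))
  off <- features$end > lens[features$replicon_id] | features$start < 0L
  if (any(off))
    stop("feature(s) outside replicon bounds: ",
         paste(features$feature_id[off], collapse = ", "))
  invisible(features)
}

#' Read a GFF3 annotation into a feature table
#'
#' GFF 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. The GFF `type` column is mapped to a feature class;
#' CDS records of at most `sorf_max_aa` amino acids are reclassified as
#' `sORF`.
#'
#' @param path GFF3 file.
#' @param source_name Annotation-source tag stored on every feature.
#' @param rank Integer authority rank of the source (1 = highest).
#' @param replicons Optional replicon list for bounds validation.
#' @param type_map Named character vector mapping GFF types to feature
#'   classes; unmapped types become `other`.
#' @param id_attribute Attribute key holding the feature identifier.
#' @param sorf_max_aa CDS at or below this protein length are labelled sORF.
#' @param category Source category (`annotated`, `ab_initio`, `in_silico`,
#'   `riboseq`), used for acceptance tiers downstream.
#' @return A list with fields `source_name`, `rank`, `category` and
#'   `features` (a feature table): an annotation set.
#' @export
read_gff <- function(path, source_name, rank = 1L, replicons = NULL,
                     type_map = c(CDS = "CDS", sORF = "sORF",
                                  five_prime_UTR = "five_prime_UTR",
                                  three_prime_UTR = "three_prime_UTR",
                                  ncRNA = "sRNA", sRNA = "sRNA",
                                  rRNA = "hkRNA", tRNA = "hkRNA",
                                  tmRNA = "hkRNA"),
                     id_attribute = "ID", sorf_max_aa = 70L,
                     category = "annotated") {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("unstranded or unknown-strand GFF features are not supported")
  ids <- if (id_attribute %in% names(md)) as.character(md[[id_attribute]])
         else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0(source_name, "_f", which(is.na(ids)))
  type <- as.character(md$type)
  fclass <- unname(type_map[type])
  fclass[is.na(fclass)] <- "other"
  ft <- feature_table(
    feature_id = ids,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    feature_class = fclass, source = source_name, replicons = replicons)
  small <- ft$feature_class == "CDS" & !is.na(ft$aa_length) &
    ft$aa_length <= sorf_max_aa
  ft$feature_class[small] <- "sORF"
  if (anyDuplicated(ft$feature_id))
    stop("duplicate feature ids within annotation source ", source_name)
  annotation_set(source_name, rank, ft, category = category)
}

#' Construct an annotation set
#'
#' @param source_name Source tag.
#' @param rank Authority rank (1 = highest).
#' @param features Feature table.
#' @param category One of `annotated`, `ab_initio`, `in_silico`, `riboseq`.
#' @export
annotation_set <- function(source_name, rank, features,
                           category = c("annotated", "ab_initio",
                                        "in_silico", "riboseq")) {
  category <- match.arg(category)
  if (anyDuplicated(features$feature_id))
    stop("feature ids must be unique within an annotation set")
  structure(list(source_name = source_name, rank = as.integer(rank),
                 category = category, features = features),
            class = "annotation_set")
}

#' Write a feature table as GFF3
#'
#' The exact inverse of [read_gff()]'s coordinate conversion: internal
#' `[start, end)` becomes 1-based inclusive `start + 1 .. end`.
#'
#' @param features Feature table.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_gff <- function(features, path, source = "riboseep") {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- ifelse(
    features$feature_class %in% c("CDS", "sORF"), "CDS",
    ifelse(features$feature_class %in% c("sRNA", "hkRNA"), "ncRNA",
           ifelse(features$feature_class == "other", "region",
                  features$feature_class)))
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$feature_class <- features$feature_class
  S4Vectors::mcols(gr)$phase <- ifelse(
    features$feature_class %in% c("CDS", "sORF"), 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Feature table -> GRanges (1-based closed coordinates).
features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$replicon_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
}

#' Extract the (stranded) nucleotide sequence of a feature
#'
#' On the minus strand the reverse complement of the forward-strand slice is
#' returned, i.e. the biological 5'-to-3' sequence.
#'
#' @param feature One-row feature table (or a list with the same fields).
#' @param replicon A replicon whose `id` matches the feature's
#'   `replicon_id`.
#' @return Nucleotide string.
#' @export
feature_sequence <- function(feature, replicon) {
  if (feature$replicon_id[[1L]] != replicon$id)
    stop("feature is on replicon '", feature$replicon_id[[1L]],
         "', not '", replicon$id, "'")
  s <- feature$start[[1L]]; e <- feature$end[[1L]]
  if (s < 0L || e > replicon$length)
    stop("feature interval outside replicon bounds")
  nt <- substr(replicon$sequence, s + 1L, e)
  if (feature$strand[[1L]] == "-") nt <- revcomp(nt) else nt
}

#' Reverse-complement a DNA string
#' @param x Nucleotide string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding nucleotide sequence
#'
#' Uses the bacterial genetic code (table 11) so GTG/TTG initiators are
#' still translated by codon value internally; the initiator is reported as
#' `M` because proteins are matched at the peptide level where N-terminal
#' methionine is the convention.
#'
#' @param nt In-frame nucleotide string, stop codon optional.
#' @param trim_stop Drop a terminal `*` if present.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nt, trim_stop = TRUE) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  if (trim_stop) aa <- sub("\\*$", "", aa)
  if (nchar(aa) > 0L) substr(aa, 1L, 1L) <- "M"
  aa
}
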