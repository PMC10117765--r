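# Integrated proteogenomic search databases (iPtgxDB-style).
#
# Annotation sources are integrated hierarchically into clusters anchored
# at the stop codon: all predicted proteins on one strand sharing the last
# base of their stop codon form one cluster, and its distinct start sites
# are its proteoforms. The most upstream proteoform contributes its full
# sequence to the search database; each shorter proteoform contributes only
# the N-terminal stretch needed to make its start-specific peptides
# observable — from its start through cleavage site (1 + max missed
# cleavages) downstream — keeping the database minimally redundant.
# Protease dialects: trypsin (cleave after K/R, not before P), LysC (after
# every K), none (no cleavage; every proteoform keeps its full sequence).

#' Six-frame in-silico ORF prediction with alternative starts
#'
#' Every stop-to-stop segment in all six reading frames is scanned for
#' start codons; up to `max_alt_starts` starts per stop (most upstream
#' first) with at least `min_aa` encoded residues are emitted.
#'
#' @param replicons Named replicon list.
#' @param min_aa Minimum protein length (aa, stop excluded).
#' @param start_codons Recognized initiation codons.
#' @param max_alt_starts Maximum start-site variants per stop.
#' @return An [annotation_set()] (`category = "in_silico"`) of ORF features.
#' @export
predict_insilico_orfs <- function(replicons, min_aa = 10L,
                                  start_codons = c("ATG", "GTG", "TTG"),
                                  max_alt_starts = 5L) {
  rows <- list()
  for (rep in replicons) {
    L <- rep$length
    for (str in c("+", "-")) {
      seqf <- if (str == "+") rep$sequence else revcomp(rep$sequence)
      for (frame in 0:2) {
        n_cod <- (L - frame) %/% 3L
        if (n_cod < min_aa + 2L) next
        cpos <- frame + 3L * (seq_len(n_cod) - 1L)   # 0-based codon starts
        codons <- substring(seqf, cpos + 1L, cpos + 3L)
        is_stop <- codons %in% STOP_CODONS
        is_start <- codons %in% start_codons
        stop_idx <- which(is_stop)
        prev_stop <- 0L
        for (si in stop_idx) {
          cand <- which(is_start[seq.int(prev_stop + 1L,
                                         max(si - 1L, prev_stop + 1L))]) +
            prev_stop
          cand <- cand[cand < si]
          prev_stop <- si
          if (!length(cand)) next
          aa_len <- si - cand    # codons from start to stop, stop excluded
          keep <- which(aa_len >= min_aa)
          if (!length(keep)) next
          keep <- keep[seq_len(min(length(keep), max_alt_starts))]
          for (ci in cand[keep]) {
            s_f <- cpos[[ci]]              # frame coords, 0-based
            e_f <- cpos[[si]] + 3L
            if (str == "+") { gs <- s_f; ge <- e_f }
            else { gs <- L - e_f; ge <- L - s_f }
            rows[[length(rows) + 1L]] <- data.frame(
              feature_id = sprintf("insilico_%s_%s_%d_%d", rep$id, str,
                                   gs, ge),
              replicon_id = rep$id, strand = str, start = gs, end = ge,
              feature_class = if (si - ci <= 70L) "sORF" else "CDS",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  ft <- do.call(rbind, rows)
  annotation_set("insilico", 99L,
                 feature_table(ft$feature_id, ft$replicon_id, ft$strand,
                               ft$start, ft$end, ft$feature_class,
                               source = "insilico"),
                 category = "in_silico")
}

# stop-codon anchor: genomic position of the last base of the stop codon
stop_anchor <- function(strand, start, end) {
  ifelse(strand == "+", end - 1L, start)
}

#' Hierarchically integrate annotation sources into proteoform clusters
#'
#' Coding features from all sources are validated against the genome (a
#' real stop codon must terminate the ORF; invalid features, e.g.
#' pseudogene fragments, are dropped and reported), then grouped by
#' (replicon, strand, stop anchor). Distinct start sites within a group
#' become proteoforms, each tagged with every source that predicted it;
#' lower-ranked sources never remove higher-ranked starts, they only add
#' proteoforms. The cluster category is that of the best-ranked
#' contributing source.
#'
#' @param sources List of [annotation_set()]s (reference/ab-initio
#'   annotations), any order; ranks decide the hierarchy.
#' @param extra Optional extra [annotation_set()]: the in-silico ORF set
#'   for a standard database, or a Ribo-seq-informed candidate set for the
#'   small custom database.
#' @param replicons Named replicon list (for sequence validation and
#'   translation).
#' @return A list with class `iptgx_clusters`: `clusters` (list), and
#'   `rejected` (feature ids that failed validation).
#' @export
integrate_annotations <- function(sources, extra = NULL, replicons) {
  sets <- c(sources, if (!is.null(extra)) list(extra))
  parts <- list(); rejected <- character()
  for (set in sets) {
    ft <- set$features
    ft <- ft[ft$feature_class %in% c("CDS", "sORF"), , drop = FALSE]
    if (nrow(ft) == 0L) next
    seqs <- vapply(names(replicons), function(r) replicons[[r]]$sequence,
                   "")
    nt <- substr(rep(seqs[ft$replicon_id], 1L), ft$start + 1L, ft$end)
    minus <- ft$strand == "-"
    if (any(minus)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(nt[minus])))
      nt[minus] <- rc
    }
    nlen <- nchar(nt)
    ok <- nlen %% 3L == 0L &
      substr(nt, nlen - 2L, nlen) %in% STOP_CODONS
    rejected <- c(rejected,
                  paste0(set$source_name, ":", ft$feature_id[!ok]))
    if (!any(ok)) next
    ft <- ft[ok, , drop = FALSE]; nt <- nt[ok]
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                             if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    substr(aa, 1L, 1L) <- "M"
    parts[[length(parts) + 1L]] <- data.frame(
      source = set$source_name, rank = set$rank, category = set$category,
      feature_id = ft$feature_id, replicon_id = ft$replicon_id,
      strand = ft$strand, start = ft$start, end = ft$end,
      anchor = stop_anchor(ft$strand, ft$start, ft$end),
      protein = aa, stringsAsFactors = FALSE)
  }
  if (!length(parts)) stop("no valid coding features to integrate")
  df <- do.call(rbind, parts)
  key <- paste(df$replicon_id, df$strand, df$anchor)
  clusters <- lapply(split(df, key), function(g) {
    # 5'-most first: ascending genomic start on +, descending end on -
    five_prime_pos <- if (g$strand[[1L]] == "+") g$start else -g$end
    starts <- sort(unique(five_prime_pos))
    proteoforms <- lapply(starts, function(sp) {
      rows <- g[five_prime_pos == sp, , drop = FALSE]
      rows <- rows[order(rows$rank, rows$source), , drop = FALSE]
      list(start = if (g$strand[[1L]] == "+") sp else -sp,
           genomic_start = min(rows$start), genomic_end = max(rows$end),
           protein = rows$protein[[1L]],
           sources = paste0(rows$source, ":", rows$feature_id),
           rank = min(rows$rank),
           category = rows$category[[which.min(rows$rank)]])
    })
    best <- which.min(vapply(proteoforms, `[[`, 0L, "rank"))
    ids <- unlist(lapply(proteoforms, `[[`, "sources"))
    pf_starts <- vapply(proteoforms, `[[`, 0L, "start")
    list(cluster_id = paste0(paste(unique(ids), collapse = ";"), "|starts=",
                             paste(pf_starts, collapse = ",")),
         replicon_id = g$replicon_id[[1L]], strand = g$strand[[1L]],
         stop_coordinate = g$anchor[[1L]],
         proteoforms = proteoforms,
         category = proteoforms[[best]]$category,
         rank = min(g$rank))
  })
  ord <- order(vapply(clusters, `[[`, "", "replicon_id"),
               vapply(clusters, `[[`, 0L, "stop_coordinate"))
  structure(list(clusters = unname(clusters[ord]), rejected = rejected),
            class = "iptgx_clusters")
}

# 1-based residue positions after which the protease cleaves
cleavage_sites <- function(protein, protease) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  if (n < 2L) return(integer())
  if (protease == "trypsin") {
    which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  } else if (protease == "lysC") {
    which(aa[-n] == "K")
  } else if (protease == "none") {
    integer()
  } else stop("unknown protease '", protease, "'")
}

#' Generate minimally redundant protein entries for one cluster
#'
#' The most upstream proteoform is emitted in full; every shorter
#' proteoform is truncated after cleavage site (1 + `max_missed_cleavages`)
#' downstream of its start (or kept in full when fewer sites exist), which
#' is exactly the stretch needed so that all of its start-specific peptides
#' with up to that many missed cleavages occur in the database. With
#' `protease = "none"` no truncation is possible and all proteoforms are
#' emitted in full.
#'
#' @param cluster One cluster from [integrate_annotations()].
#' @param protease `trypsin`, `lysC` or `none`.
#' @param max_missed_cleavages Missed cleavages the search allows.
#' @return `data.frame` of entries: `entry_id`, `cluster_id`, `proteoform`,
#'   `sequence`, `full_length`, `protease`.
#' @export
generate_entries <- function(cluster,
                             protease = c("trypsin", "lysC", "none"),
                             max_missed_cleavages = 2L) {
  protease <- match.arg(protease)
  pf <- cluster$proteoforms
  out <- lapply(seq_along(pf), function(i) {
    p <- pf[[i]]$protein
    if (i == 1L || protease == "none") {
      seqn <- p; full <- TRUE
    } else {
      sites <- cleavage_sites(p, protease)
      need <- 1L + max_missed_cleavages
      if (length(sites) >= need) {
        seqn <- substr(p, 1L, sites[[need]]); full <- FALSE
      } else {
        seqn <- p; full <- TRUE
      }
    }
    data.frame(entry_id = sprintf("%s|pf%d", cluster_short_id(cluster), i),
               cluster_id = cluster$cluster_id, proteoform = i,
               sequence = seqn, full_length = full, protease = protease,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

cluster_short_id <- function(cluster) {
  sprintf("%s_%s_%d", cluster$replicon_id, cluster$strand,
          cluster$stop_coordinate)
}

#' Build a search database from clusters
#'
#' @param clusters An `iptgx_clusters` object.
#' @param protease Protease dialect.
#' @param max_missed_cleavages Missed cleavages allowed downstream.
#' @param contaminants Optional amino-acid sequences (named character
#'   vector, e.g. read from a cRAP-style FASTA) appended as-is.
#' @return A list with class `iptgx_db`: `entries` (data.frame),
#'   `clusters`, `protease`.
#' @export
build_db <- function(clusters, protease = c("trypsin", "lysC", "none"),
                     max_missed_cleavages = 2L, contaminants = NULL) {
  protease <- match.arg(protease)
  entries <- do.call(rbind, lapply(clusters$clusters, generate_entries,
                                   protease = protease,
                                   max_missed_cleavages =
                                     max_missed_cleavages))
  if (!is.null(contaminants)) {
    entries <- rbind(entries, data.frame(
      entry_id = paste0("CONT_", names(contaminants)),
      cluster_id = NA_character_, proteoform = NA_integer_,
      sequence = unname(contaminants), full_length = TRUE,
      protease = protease, stringsAsFactors = FALSE))
  }
  structure(list(entries = entries, clusters = clusters,
                 protease = protease,
                 max_missed_cleavages = max_missed_cleavages),
            class = "iptgx_db")
}

#' Write a search database as protein FASTA plus coordinate GFF3
#'
#' FASTA headers carry the entry id, category and composite cluster
#' identifier; the GFF maps each proteoform back to genomic coordinates so
#' experimental evidence can be overlaid on the genome. Output ordering is
#' deterministic (replicon, stop anchor, proteoform).
#'
#' @param db An `iptgx_db`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_iptgxdb <- function(db, fasta_path, gff_path) {
  ent <- db$entries[!is.na(db$entries$cluster_id), , drop = FALSE]
  cl <- db$clusters$clusters
  cat_of <- stats::setNames(vapply(cl, `[[`, "", "category"),
                            vapply(cl, `[[`, "", "cluster_id"))
  headers <- sprintf("%s category=%s cluster=%s",
                     ent$entry_id, cat_of[ent$cluster_id], ent$cluster_id)
  ss <- Biostrings::AAStringSet(ent$sequence)
  names(ss) <- headers
  cont <- db$entries[is.na(db$entries$cluster_id), , drop = FALSE]
  if (nrow(cont)) {
    cs <- Biostrings::AAStringSet(cont$sequence)
    names(cs) <- cont$entry_id
    ss <- c(ss, cs)
  }
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  rows <- list()
  for (c in cl) {
    for (i in seq_along(c$proteoforms)) {
      p <- c$proteoforms[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s|pf%d", cluster_short_id(c), i),
        replicon_id = c$replicon_id, strand = c$strand,
        start = p$genomic_start, end = p$genomic_end,
        feature_class = if ((p$genomic_end - p$genomic_start) / 3L - 1L <=
                              70L) "sORF" else "CDS",
        stringsAsFactors = FALSE)
    }
  }
  ft <- do.call(rbind, rows)
  write_gff(feature_table(ft$feature_id, ft$replicon_id, ft$strand,
                          ft$start, ft$end, ft$feature_class,
                          source = "iptgxdb"), gff_path)
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' Read a protein FASTA back into an entry table
#' @param path FASTA path.
#' @return `data.frame` with `entry_id`, `sequence` and, when present in
#'   the header, `cluster_id`.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  cluster <- ifelse(grepl("cluster=", hdr),
                    sub(".*cluster=(\\S+).*", "\\1", hdr), NA_character_)
  data.frame(entry_id = id, cluster_id = cluster,
             sequence = as.character(ss), stringsAsFactors = FALSE)
}
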