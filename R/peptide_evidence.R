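# In-silico digestion, peptide ambiguity classification and tiered
# PSM-based protein acceptance.
#
# Peptide classes against one database build:
#   1a — found in a single cluster that has a single proteoform
#   2a — single cluster, proper subset of its proteoforms (start-specific)
#   2b — single cluster, all of its proteoforms (gene-level evidence)
#   3a — several clusters whose matched protein sequences are identical
#        (identical gene copies); unambiguous in sequence
#   ambiguous — anything else
#
# Acceptance tiers (per cluster): proteins of >= 15 kDa need two unique
# peptides regardless of category; below 15 kDa, annotated proteins need
# one unique peptide with >= 2 PSMs, ab initio predictions >= 3 PSMs, and
# in-silico/Ribo-seq predictions >= 4 PSMs, or 3 PSMs when observed in each
# of the three replicates.

#' In-silico protease digestion
#'
#' @param protein Amino-acid string.
#' @param protease `trypsin` (cleave after K/R except before P), `lysC`
#'   (after every K) or `none` (all substrings within `nonspecific_len`).
#' @param max_missed Maximum internal missed cleavage sites per peptide
#'   (ignored for `none`).
#' @param nonspecific_len Length bounds for `none`.
#' @return Character vector of peptides (unique, order of first
#'   occurrence).
#' @export
digest <- function(protein, protease = c("trypsin", "lysC", "none"),
                   max_missed = 2L, nonspecific_len = c(5L, 30L)) {
  protease <- match.arg(protease)
  n <- nchar(protein)
  if (n == 0L) return(character())
  if (protease == "none") {
    lo <- nonspecific_len[[1L]]; hi <- min(nonspecific_len[[2L]], n)
    if (lo > n) return(character())
    peps <- unlist(lapply(lo:hi, function(l)
      substring(protein, seq_len(n - l + 1L), seq_len(n - l + 1L) + l - 1L)))
    return(unique(peps))
  }
  sites <- cleavage_sites(protein, protease)
  bounds <- c(0L, sites, n)
  out <- character()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:min(i + max_missed, length(bounds) - 1L)) {
      out <- c(out, substr(protein, bounds[[i]] + 1L, bounds[[j + 1L]]))
    }
  }
  unique(out)
}

#' Classify a peptide's ambiguity against a database
#'
#' Matching is substring containment in the full proteoform sequences of
#' the clusters (not the truncated search entries).
#'
#' @param peptide Amino-acid string.
#' @param clusters An `iptgx_clusters` object.
#' @return A list: `class` (`1a`, `2a`, `2b`, `3a`, `ambiguous` or
#'   `unmatched`) and `clusters` (indices of matched clusters).
#' @export
classify_peptide <- function(peptide, clusters) {
  cl <- clusters$clusters
  hits <- list()
  for (i in seq_along(cl)) {
    pf_hit <- which(vapply(cl[[i]]$proteoforms, function(p)
      grepl(peptide, p$protein, fixed = TRUE), TRUE))
    if (length(pf_hit)) hits[[length(hits) + 1L]] <-
        list(cluster = i, proteoforms = pf_hit)
  }
  if (!length(hits))
    return(list(class = "unmatched", clusters = integer()))
  cidx <- vapply(hits, `[[`, 0L, "cluster")
  if (length(hits) == 1L) {
    n_pf <- length(cl[[cidx]]$proteoforms)
    k <- length(hits[[1L]]$proteoforms)
    cls <- if (n_pf == 1L) "1a" else if (k < n_pf) "2a" else "2b"
    return(list(class = cls, clusters = cidx))
  }
  seqs <- unlist(lapply(hits, function(h)
    vapply(cl[[h$cluster]]$proteoforms[h$proteoforms],
           `[[`, "", "protein")))
  if (length(unique(seqs)) == 1L)
    return(list(class = "3a", clusters = cidx))
  list(class = "ambiguous", clusters = cidx)
}

#' Classify every peptide of a PSM table
#'
#' @param psms PSM table with `peptide_sequence`.
#' @param clusters An `iptgx_clusters` object.
#' @return `data.frame`: `peptide_sequence`, `class`, `cluster_ids`
#'   (comma-separated indices into `clusters$clusters`).
#' @export
classify_peptides <- function(psms, clusters) {
  peps <- unique(psms$peptide_sequence)
  res <- lapply(peps, classify_peptide, clusters = clusters)
  data.frame(peptide_sequence = peps,
             class = vapply(res, `[[`, "", "class"),
             cluster_ids = vapply(res, function(x)
               paste(x$clusters, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' Average protein mass in kDa
#'
#' Sum of average residue masses plus one water; the empty chain therefore
#' weighs one water.
#'
#' @param sequence Amino-acid string (standard 20 residues).
#' @return Mass in kDa.
#' @export
protein_mass <- function(sequence) {
  masses <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
              V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
              I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
              K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
              F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(aa, names(masses))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  (sum(masses[aa]) + 18.0153) / 1000
}

#' Tiered PSM-based acceptance decision for one cluster
#'
#' Unique evidence is carried by peptides of class 1a, 2a (configurable)
#' and 3a; class 2b peptides add gene-level PSM support; ambiguous peptides
#' are excluded. The protein mass is that of the best-ranked proteoform.
#' Exactly 15 kDa falls in the two-unique-peptide regime.
#'
#' @param cluster One cluster from [integrate_annotations()].
#' @param psms PSM table rows (`peptide_sequence`, `replicate_id`,
#'   `psm_count`) — all PSMs of the experiment; rows whose peptide maps to
#'   this cluster are selected via `classes`.
#' @param classes Output of [classify_peptides()] for the same table.
#' @param cluster_index Index of `cluster` within the classified database.
#' @param unique_classes Peptide classes counted as unique evidence.
#' @param n_replicates_required Replicates needed for the 3-PSM in-silico
#'   path.
#' @return A one-row `data.frame`: `cluster_id`, `category`, `mass_kda`,
#'   `unique_peptides`, `total_psms`, `n_replicates`, `accepted`,
#'   `rule_applied`.
#' @export
accept_protein <- function(cluster, psms, classes, cluster_index,
                           unique_classes = c("1a", "2a", "3a"),
                           n_replicates_required = 3L) {
  in_cluster <- vapply(strsplit(classes$cluster_ids, ","), function(x)
    as.character(cluster_index) %in% x, TRUE)
  evid <- classes[in_cluster & classes$class %in%
                    c(unique_classes, "2b"), , drop = FALSE]
  uniq <- evid$peptide_sequence[evid$class %in% unique_classes]
  rows <- psms[psms$peptide_sequence %in% evid$peptide_sequence, ,
               drop = FALSE]
  total_psms <- sum(rows$psm_count)
  reps <- unique(rows$replicate_id)
  best <- which.min(vapply(cluster$proteoforms, `[[`, 0L, "rank"))
  mass <- protein_mass(cluster$proteoforms[[best]]$protein)
  n_uniq <- length(unique(uniq))
  category <- cluster$category
  if (mass >= 15) {
    accepted <- n_uniq >= 2L
    rule <- "ge15kDa_two_unique_peptides"
  } else if (category == "annotated") {
    accepted <- n_uniq >= 1L && total_psms >= 2L
    rule <- "lt15kDa_annotated_2psm"
  } else if (category == "ab_initio") {
    accepted <- n_uniq >= 1L && total_psms >= 3L
    rule <- "lt15kDa_ab_initio_3psm"
  } else {  # in_silico or riboseq predictions
    per_rep <- tapply(rows$psm_count, rows$replicate_id, sum)
    all_reps <- length(per_rep) >= n_replicates_required &&
      all(per_rep >= 1L)
    if (n_uniq >= 1L && total_psms >= 4L) {
      accepted <- TRUE; rule <- "lt15kDa_in_silico_4psm"
    } else if (n_uniq >= 1L && total_psms >= 3L && all_reps) {
      accepted <- TRUE; rule <- "lt15kDa_in_silico_3psm_all_replicates"
    } else {
      accepted <- FALSE; rule <- "lt15kDa_in_silico_4psm"
    }
  }
  data.frame(cluster_id = cluster$cluster_id, category = category,
             mass_kda = mass, unique_peptides = n_uniq,
             total_psms = total_psms, n_replicates = length(reps),
             accepted = accepted, rule_applied = rule,
             stringsAsFactors = FALSE)
}

#' Acceptance decisions for every cluster of a database
#'
#' @param clusters An `iptgx_clusters` object.
#' @param psms PSM table.
#' @param unique_classes See [accept_protein()].
#' @return `data.frame` of decisions, one row per cluster (the master-table
#'   analogue).
#' @export
accept_proteins <- function(clusters, psms,
                            unique_classes = c("1a", "2a", "3a")) {
  classes <- classify_peptides(psms, clusters)
  out <- lapply(seq_along(clusters$clusters), function(i)
    accept_protein(clusters$clusters[[i]], psms, classes, i,
                   unique_classes = unique_classes))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
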