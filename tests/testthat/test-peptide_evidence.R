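test_that("protease digestion follows the cleavage rules", {
  expect_setequal(digest("MKRAPK", "trypsin", max_missed = 0L),
                  c("MK", "R", "APK"))
  expect_equal(digest("AKPR", "trypsin", max_missed = 0L), "AKPR")
  expect_setequal(digest("AKPK", "lysC", max_missed = 0L), c("AK", "PK"))
  # missed cleavages add concatenated fragments
  expect_setequal(digest("MKRAPK", "trypsin", max_missed = 1L),
                  c("MK", "R", "APK", "MKR", "RAPK"))
  expect_error(digest("MK", "pepsin"))
})

test_that("non-specific digestion enumerates all substrings within bounds", {
  p <- "MKRAPKW"
  got <- digest(p, "none", nonspecific_len = c(3L, 5L))
  n <- nchar(p)
  oracle <- unique(unlist(lapply(3:5, function(l)
    vapply(seq_len(n - l + 1L), function(s)
      substr(p, s, s + l - 1L), ""))))
  expect_setequal(got, oracle)
})

# database with the ambiguity structures: single-proteoform cluster,
# two-proteoform cluster, identical gene copies, and a near-duplicate pair
classification_fixture <- function() {
  memo("classification_fixture", {
    orf <- function(aas) {
      codon <- c(M = "ATG", K = "AAA", P = "CCC", G = "GGA", F = "TTT",
                 V = "GTT", L = "CTT", R = "CGT", T = "ACT", W = "TGG",
                 A = "GCT", S = "TCT")
      paste0(paste(codon[strsplit(aas, "")[[1L]]], collapse = ""), "TAA")
    }
    seg <- c(orf("MKPGFVLRTW"),          # cluster 1: single proteoform
             "CC",
             orf("MAAKTTTKGGGKLS"),      # cluster 2: two starts (below)
             "G",
             orf("MWWLRVFS"),            # clusters 3+4: identical copies
             "TT",
             orf("MWWLRVFS"),
             "A",
             orf("MWWLRVFT"))            # cluster 5: near-duplicate
    sq <- paste(seg, collapse = "")
    reps <- list(chr = replicon("chr", sq))
    offs <- cumsum(c(0L, nchar(seg)))[seq_along(seg)]
    ft <- function(id, i, ...) {
      s <- offs[[i]]
      feature_table(id, "chr", "+", s, s + nchar(seg[[i]]), "CDS", ...)
    }
    a <- annotation_set("A", 1L, rbind(
      ft("c1", 1L), ft("c2_long", 3L), ft("c3", 5L), ft("c4", 7L),
      ft("c5", 9L)))
    # second source: shorter start for cluster 2 (skip "MAA", 9 nt in)
    s2 <- offs[[3L]] + 9L
    b <- annotation_set("B", 2L, feature_table(
      "c2_short", "chr", "+", s2, offs[[3L]] + nchar(seg[[3L]]), "CDS",
      "B"), category = "ab_initio")
    cl <- integrate_annotations(list(a, b), replicons = reps)
    list(reps = reps, clusters = cl)
  })
}

test_that("peptide ambiguity classes follow their definitions", {
  fx <- classification_fixture()
  cl <- fx$clusters
  # unique to the single-proteoform cluster
  expect_equal(classify_peptide("KPGFVLR", cl)$class, "1a")
  # start-specific: upstream of the short proteoform's start
  expect_equal(classify_peptide("MAAK", cl)$class, "2a")
  # shared by all proteoforms of one cluster
  expect_equal(classify_peptide("TTTKGGGK", cl)$class, "2b")
  # identical gene copies: unambiguous sequence, several loci
  expect_equal(classify_peptide("MWWLRVFS", cl)$class, "3a")
  # shared by non-identical proteins of different clusters
  expect_equal(classify_peptide("MWWLR", cl)$class, "ambiguous")
  expect_equal(classify_peptide("QQQQQQ", cl)$class, "unmatched")
})

test_that("classification equals a brute-force substring scan on random
          peptides", {
  fx <- classification_fixture()
  cl <- fx$clusters
  prots <- lapply(cl$clusters, function(c)
    vapply(c$proteoforms, `[[`, "", "protein"))
  set.seed(55)
  all_seq <- unlist(prots)
  peps <- unique(unlist(lapply(1:80, function(i) {
    p <- sample(all_seq, 1L)
    l <- sample(3:8, 1L)
    if (nchar(p) < l) return(NULL)
    s <- sample.int(nchar(p) - l + 1L, 1L)
    substr(p, s, s + l - 1L)
  })))
  for (pep in peps) {
    hit_cl <- which(vapply(prots, function(ps)
      any(grepl(pep, ps, fixed = TRUE)), TRUE))
    expected <- if (length(hit_cl) == 0L) "unmatched"
    else if (length(hit_cl) == 1L) {
      ps <- prots[[hit_cl]]
      k <- sum(grepl(pep, ps, fixed = TRUE))
      if (length(ps) == 1L) "1a" else if (k < length(ps)) "2a" else "2b"
    } else {
      matched <- unlist(lapply(hit_cl, function(i)
        prots[[i]][grepl(pep, prots[[i]], fixed = TRUE)]))
      if (length(unique(matched)) == 1L) "3a" else "ambiguous"
    }
    expect_equal(classify_peptide(pep, cl)$class, expected, info = pep)
  }
})

test_that("protein mass uses average residue masses plus one water", {
  expect_equal(protein_mass(""), 18.0153 / 1000)
  expect_equal(protein_mass("G") * 1000, 57.0519 + 18.0153,
               tolerance = 1e-6)
  # additivity: mass(AB) = mass(A) + mass(B) - water
  m_ab <- protein_mass("GW")
  expect_equal(m_ab, protein_mass("G") + protein_mass("W") - 18.0153 / 1000,
               tolerance = 1e-9)
  expect_error(protein_mass("GXZ"), "unknown residue")
})

# helper: cluster with a given protein/category and a PSM table
tier_case <- function(protein, category, psms_per_rep) {
  cluster <- list(cluster_id = "t", replicon_id = "chr", strand = "+",
                  stop_coordinate = 1L,
                  proteoforms = list(list(start = 0L, genomic_start = 0L,
                                          genomic_end = 3L,
                                          protein = protein,
                                          sources = "A:x", rank = 1L,
                                          category = category)),
                  category = category, rank = 1L)
  psms <- do.call(rbind, lapply(seq_along(psms_per_rep), function(r)
    if (psms_per_rep[[r]] > 0L)
      data.frame(peptide_sequence = substr(protein, 2L, 7L),
                 replicate_id = sprintf("rep%d", r),
                 psm_count = psms_per_rep[[r]])))
  classes <- data.frame(peptide_sequence = substr(protein, 2L, 7L),
                        class = "1a", cluster_ids = "1")
  accept_protein(cluster, psms, classes, 1L)
}

test_that("tiered PSM acceptance matches the published rules", {
  small <- paste(rep("GAVLIP", 12L), collapse = "")   # ~6.6 kDa
  # annotated < 15 kDa: one unique peptide with two PSMs suffices
  expect_true(tier_case(small, "annotated", c(2L, 0L, 0L))$accepted)
  expect_false(tier_case(small, "annotated", c(1L, 0L, 0L))$accepted)
  # ab initio needs 3 PSMs
  expect_false(tier_case(small, "ab_initio", c(2L, 0L, 0L))$accepted)
  expect_true(tier_case(small, "ab_initio", c(2L, 1L, 0L))$accepted)
  # in silico: 3 PSMs split 2+1 over two replicates is rejected ...
  expect_false(tier_case(small, "in_silico", c(2L, 1L, 0L))$accepted)
  # ... but 3 PSMs, one in each of three replicates, is accepted
  expect_true(tier_case(small, "in_silico", c(1L, 1L, 1L))$accepted)
  # ... and 4 PSMs accepted regardless of replicate structure
  expect_true(tier_case(small, "in_silico", c(4L, 0L, 0L))$accepted)
  # >= 15 kDa requires two unique peptides however many PSMs accrue
  big <- paste(rep("GAVLIPWFKR", 20L), collapse = "")  # ~23 kDa
  expect_false(tier_case(big, "annotated", c(10L, 10L, 10L))$accepted)
})

test_that("acceptance is monotone in evidence", {
  small <- paste(rep("GAVLIP", 12L), collapse = "")
  base <- tier_case(small, "in_silico", c(1L, 1L, 1L))
  more <- tier_case(small, "in_silico", c(2L, 2L, 2L))
  expect_true(base$accepted)
  expect_true(more$accepted)
  # adding a second unique peptide flips a rejected >=15 kDa case
  big <- paste(rep("GAVLIPWFKR", 20L), collapse = "")
  cluster <- list(cluster_id = "t", replicon_id = "chr", strand = "+",
                  stop_coordinate = 1L,
                  proteoforms = list(list(start = 0L, genomic_start = 0L,
                                          genomic_end = 3L, protein = big,
                                          sources = "A:x", rank = 1L,
                                          category = "annotated")),
                  category = "annotated", rank = 1L)
  peps <- c(substr(big, 2L, 9L), substr(big, 5L, 14L))
  psms <- data.frame(peptide_sequence = peps, replicate_id = "rep1",
                     psm_count = c(5L, 2L))
  classes <- data.frame(peptide_sequence = peps, class = "1a",
                        cluster_ids = "1")
  expect_true(accept_protein(cluster, psms, classes, 1L)$accepted)
})

test_that("expressed truth proteins are accepted and unexpressed ones are
          not, on simulated PSM tables", {
  sim <- small_sim()
  g <- sim$genome
  # database over every truth ORF (translated and decoys)
  tt <- g$truth
  all_set <- annotation_set(
    "truth", 1L,
    feature_table(tt$feature_id, tt$replicon_id, tt$strand, tt$start,
                  tt$end, "CDS", "truth"))
  cl <- integrate_annotations(list(all_set), replicons = g$replicons)
  psms <- simulate_psms(g, "trypsin", sim$config)
  dec <- accept_proteins(cl, psms)
  # map clusters back to truth features via the composite identifier
  feat_of <- vapply(strsplit(dec$cluster_id, "\\|"), function(x)
    sub("^truth:", "", strsplit(x[[1L]], ";")[[1L]][[1L]]), "")
  translated <- tt$translated[match(feat_of, tt$feature_id)]
  # no unexpressed (decoy) protein is accepted in the zero-noise setting
  expect_true(all(!dec$accepted[!translated]))
  # expressed proteins with enough simulated evidence are accepted
  enough <- dec$total_psms >= 4L & dec$unique_peptides >= 2L
  expect_true(all(dec$accepted[translated & enough]))
  expect_gt(sum(dec$accepted[translated]), 0L)
})
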