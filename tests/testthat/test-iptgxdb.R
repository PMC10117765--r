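# brute-force six-frame scanner used as the independent oracle
oracle_orfs <- function(seqs, min_aa, starts = c("ATG", "GTG", "TTG"),
                        max_alt = 5L) {
  stops <- c("TAA", "TAG", "TGA")
  count <- 0L
  for (nm in names(seqs)) {
    for (str in c("+", "-")) {
      sq <- if (str == "+") seqs[[nm]] else revcomp(seqs[[nm]])
      L <- nchar(sq)
      for (fr in 0:2) {
        codons <- substring(sq, seq(fr + 1L, L - 2L, by = 3L),
                            seq(fr + 3L, L, by = 3L))
        prev <- 0L
        for (si in which(codons %in% stops)) {
          cand <- c()
          for (ci in seq(prev + 1L, length.out = max(si - prev - 1L, 0L)))
            if (codons[[ci]] %in% starts && si - ci >= min_aa)
              cand <- c(cand, ci)
          count <- count + min(length(cand), max_alt)
          prev <- si
        }
      }
    }
  }
  count
}

test_that("six-frame ORF prediction translates minimal cases correctly", {
  rep <- list(chr = replicon("chr", "ATGAAATAA"))
  ann <- predict_insilico_orfs(rep, min_aa = 1L)
  expect_equal(nrow(ann$features), 1L)
  f <- ann$features[1L, ]
  expect_equal(feature_sequence(f, rep$chr), "ATGAAATAA")
  expect_equal(translate_cds(feature_sequence(f, rep$chr)), "MK")
})

test_that("alternative starts yield several proteoform starts per stop", {
  # two in-frame ATGs upstream of one stop
  rep <- list(chr = replicon("chr", "ATGAAAATGAAAAAATAA"))
  ann <- predict_insilico_orfs(rep, min_aa = 1L, max_alt_starts = 5L)
  plus_f0 <- ann$features[ann$features$strand == "+" &
                            ann$features$end == 18L, ]
  expect_equal(nrow(plus_f0), 2L)
  expect_equal(sort(plus_f0$start), c(0L, 6L))
  # capped by max_alt_starts, most upstream kept first
  ann1 <- predict_insilico_orfs(rep, min_aa = 1L, max_alt_starts = 1L)
  one <- ann1$features[ann1$features$strand == "+" &
                         ann1$features$end == 18L, ]
  expect_equal(one$start, 0L)
})

test_that("ORF count on random sequence matches the brute-force scanner", {
  set.seed(9)
  sq <- paste(sample(c("A", "C", "G", "T"), 10000L, TRUE), collapse = "")
  reps <- list(chr = replicon("chr", sq))
  for (min_aa in c(5L, 10L)) {
    ann <- predict_insilico_orfs(reps, min_aa = min_aa)
    expect_equal(nrow(ann$features),
                 oracle_orfs(list(chr = sq), min_aa), info = min_aa)
  }
})

# small two-source genome used across the integration tests
integration_fixture <- function() {
  # cluster with two starts: long ORF 0..24, short 6..24 (+ strand)
  sq <- paste0("ATGAAA", "ATGCCCAAAGGGTTT", "TAA",          # 0..24
               "CCGG",
               "ATGGTTAAACCC", "TAG",                        # 28..43
               paste(rep("A", 20), collapse = ""))
  reps <- list(chr = replicon("chr", sq))
  long <- feature_table("g1_long", "chr", "+", 0L, 24L, "CDS", "A")
  short <- feature_table("g1_short", "chr", "+", 6L, 24L, "CDS", "B")
  second <- feature_table("g2", "chr", "+", 28L, 43L, "CDS", "A")
  a <- annotation_set("A", 1L, rbind(long, second))
  b <- annotation_set("B", 2L, short, category = "ab_initio")
  list(reps = reps, a = a, b = b)
}

test_that("agreeing sources give one proteoform with both source tags", {
  fx <- integration_fixture()
  b2 <- annotation_set("B", 2L, fx$a$features, category = "ab_initio")
  cl <- integrate_annotations(list(fx$a, b2), replicons = fx$reps)
  expect_length(cl$clusters, 2L)
  c1 <- cl$clusters[[1L]]
  expect_length(c1$proteoforms, 1L)
  expect_length(c1$proteoforms[[1L]]$sources, 2L)
  expect_equal(c1$category, "annotated")  # best rank wins
})

test_that("sources sharing a stop but not a start form one two-proteoform
          cluster ordered upstream-first", {
  fx <- integration_fixture()
  cl <- integrate_annotations(list(fx$a, fx$b), replicons = fx$reps)
  expect_length(cl$clusters, 2L)
  c1 <- cl$clusters[[which(vapply(cl$clusters, `[[`, 0L,
                                  "stop_coordinate") == 23L)]]
  expect_length(c1$proteoforms, 2L)
  expect_equal(c1$proteoforms[[1L]]$protein, "MKMPKGF")   # most upstream
  expect_equal(c1$proteoforms[[2L]]$protein, "MPKGF")
})

test_that("cluster count equals the number of distinct stop anchors", {
  set.seed(33)
  sq <- paste(sample(c("A", "C", "G", "T"), 12000L, TRUE), collapse = "")
  reps <- list(chr = replicon("chr", sq))
  ins <- predict_insilico_orfs(reps, min_aa = 8L, max_alt_starts = 3L)
  cl <- integrate_annotations(list(ins), replicons = reps)
  ft <- ins$features
  anchors <- unique(paste(ft$replicon_id, ft$strand,
                          ifelse(ft$strand == "+", ft$end - 1L, ft$start)))
  expect_length(cl$clusters, length(anchors))
  # entry count equals total proteoform count
  db <- build_db(cl, "trypsin")
  expect_equal(nrow(db$entries),
               sum(vapply(cl$clusters, function(c)
                 length(c$proteoforms), 0L)))
})

test_that("features without a genuine stop codon are rejected, not kept", {
  reps <- list(chr = replicon("chr", "ATGAAAAAATAAATGCCC"))
  good <- feature_table("ok", "chr", "+", 0L, 12L, "CDS", "A")
  pseudo <- feature_table("pseudo", "chr", "+", 12L, 18L, "CDS", "A")
  a <- annotation_set("A", 1L, rbind(good, pseudo))
  cl <- integrate_annotations(list(a), replicons = reps)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$rejected, "A:pseudo")
})

test_that("child entries span exactly (1 + missed) cleavage sites", {
  cluster <- list(
    cluster_id = "t", replicon_id = "chr", strand = "+",
    stop_coordinate = 100L,
    proteoforms = list(
      list(start = 0L, genomic_start = 0L, genomic_end = 36L,
           protein = "MAKTTTKGGGK", sources = "A:p", rank = 1L,
           category = "annotated"),
      list(start = 12L, genomic_start = 12L, genomic_end = 36L,
           protein = "TTKGGGK", sources = "B:c", rank = 2L,
           category = "ab_initio")),
    category = "annotated", rank = 1L)
  e0 <- generate_entries(cluster, "trypsin", max_missed_cleavages = 0L)
  expect_equal(e0$sequence, c("MAKTTTKGGGK", "TTK"))
  e2 <- generate_entries(cluster, "trypsin", max_missed_cleavages = 2L)
  expect_equal(e2$sequence, c("MAKTTTKGGGK", "TTKGGGK"))
  en <- generate_entries(cluster, "none")
  expect_equal(en$sequence, c("MAKTTTKGGGK", "TTKGGGK"))
})

test_that("every peptide of every proteoform occurs in some entry
          (completeness), and truncation is minimal", {
  set.seed(41)
  sq <- paste(sample(c("A", "C", "G", "T"), 60000L, TRUE), collapse = "")
  reps <- list(chr = replicon("chr", sq))
  ins <- predict_insilico_orfs(reps, min_aa = 15L, max_alt_starts = 3L)
  cl <- integrate_annotations(list(ins), replicons = reps)
  multi <- Filter(function(c) length(c$proteoforms) > 1L, cl$clusters)
  expect_gt(length(multi), 10L)
  multi <- multi[seq_len(min(200L, length(multi)))]
  mm <- 2L
  for (protease in c("trypsin", "lysC")) {
    for (cluster in multi) {
      entries <- generate_entries(cluster, protease,
                                  max_missed_cleavages = mm)
      for (p in cluster$proteoforms) {
        peps <- digest(p$protein, protease, max_missed = mm)
        found <- vapply(peps, function(pep)
          any(grepl(pep, entries$sequence, fixed = TRUE)), TRUE)
        expect_true(all(found), info = protease)
      }
    }
  }
  # minimality: dropping the last residue of a truncated child entry breaks
  # completeness for one of its start-specific peptides. Children whose
  # start codon is an internal ATG of the parent are skipped: their peptides
  # also occur in the parent's full sequence, so no truncation of theirs can
  # break completeness.
  checked <- FALSE
  for (cluster in multi) {
    entries <- generate_entries(cluster, "trypsin",
                                max_missed_cleavages = mm)
    for (i in which(!entries$full_length)) {
      p <- cluster$proteoforms[[entries$proteoform[i]]]
      parent <- cluster$proteoforms[[1L]]$protein
      if (grepl(p$protein, parent, fixed = TRUE)) next
      trimmed <- entries$sequence
      trimmed[i] <- substr(trimmed[i], 1L, nchar(trimmed[i]) - 1L)
      peps <- digest(p$protein, "trypsin", max_missed = mm)
      still <- vapply(peps, function(pep)
        any(grepl(pep, trimmed, fixed = TRUE)), TRUE)
      expect_false(all(still))
      checked <- TRUE
      break
    }
    if (checked) break
  }
  expect_true(checked)
})

test_that("integration is idempotent and invariant to equal-rank permutation", {
  fx <- integration_fixture()
  cl1 <- integrate_annotations(list(fx$a, fx$b), replicons = fx$reps)
  # re-integrating the integrated proteoform coordinates yields the same
  # clusters
  rows <- do.call(rbind, lapply(cl1$clusters, function(c)
    do.call(rbind, lapply(seq_along(c$proteoforms), function(i)
      data.frame(id = sprintf("%s_%s_%d_%d", c$replicon_id, c$strand,
                              c$stop_coordinate, i),
                 rid = c$replicon_id, strand = c$strand,
                 s = c$proteoforms[[i]]$genomic_start,
                 e = c$proteoforms[[i]]$genomic_end)))))
  again <- annotation_set("again", 1L,
                          feature_table(rows$id, rows$rid, rows$strand,
                                        rows$s, rows$e, "CDS", "again"))
  cl2 <- integrate_annotations(list(again), replicons = fx$reps)
  key <- function(cl) lapply(cl$clusters, function(c)
    list(c$stop_coordinate, c$strand,
         lapply(c$proteoforms, `[[`, "protein")))
  expect_equal(key(cl2), key(cl1))
  # permuting equal-rank sources never changes cluster membership
  b_eq <- annotation_set("B", 1L, fx$b$features, category = "ab_initio")
  cl_ab <- integrate_annotations(list(fx$a, b_eq), replicons = fx$reps)
  cl_ba <- integrate_annotations(list(b_eq, fx$a), replicons = fx$reps)
  expect_equal(key(cl_ab), key(cl_ba))
})

test_that("database FASTA/GFF round trip and the custom database is
          smaller than the standard one", {
  sim <- small_sim()
  g <- sim$genome
  standard <- integrate_annotations(
    list(g$annotation), predict_insilico_orfs(g$replicons, min_aa = 10L),
    g$replicons)
  tr <- g$truth[g$truth$translated & !g$truth$annotated, ]
  ribo_set <- annotation_set(
    "riboseq", 50L,
    feature_table(tr$feature_id, tr$replicon_id, tr$strand, tr$start,
                  tr$end, "sORF", "riboseq"), category = "riboseq")
  custom <- integrate_annotations(list(g$annotation), ribo_set,
                                  g$replicons)
  db_std <- build_db(standard, "trypsin")
  db_cus <- build_db(custom, "trypsin")
  expect_lt(nrow(db_cus$entries), nrow(db_std$entries))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_iptgxdb(db_cus, fa, gf)
  back <- read_protein_fasta(fa)
  expect_equal(sort(back$sequence), sort(db_cus$entries$sequence))
  coords <- read_gff(gf, "db")
  expect_equal(nrow(coords$features),
               sum(vapply(custom$clusters, function(c)
                 length(c$proteoforms), 0L)))
})
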