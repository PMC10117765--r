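Package: riboseep
Title: Bacterial Translatome Mapping and Small Protein Discovery from
    Ribosome Profiling and Proteogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a bacterial translatome from paired
    ribosome profiling (Ribo-seq) and RNA-seq data and for discovering
    small ORF-encoded proteins (SEPs). Implements strand-aware coverage
    tracks with per-million and minimum-library normalization, per-feature
    RPKM and translation efficiency, metagene diagnostics of the
    initiation signature, translation-filter cascades with quantitative
    curation heuristics for small ORF calls, hierarchical integration of
    multiple genome annotations into stop-codon-anchored proteoform
    clusters, protease-specific minimally redundant proteogenomic search
    databases, peptide ambiguity classification, and tiered
    peptide-spectrum-match protein acceptance. A deterministic simulator
    generates toy genomes, footprint and RNA-seq alignments, candidate
    ORF score tables, and PSM tables with ground truth for end-to-end
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), Rsamtools, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
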