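---
title: "Mapping a bacterial translatome and discovering small proteins with riboseep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a bacterial translatome and discovering small proteins with riboseep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboseep)
```

## The problem

Small ORF-encoded proteins (SEPs, here proteins of at most 70 amino acids)
are systematically under-annotated in bacterial genomes and hard to detect
by shotgun proteomics alone. Ribosome profiling (Ribo-seq) — sequencing the
~30 nt mRNA footprints protected by translating ribosomes — detects
translation directly and with high sensitivity, and proteogenomic searches
against databases that go beyond the reference annotation can confirm the
predicted products by mass spectrometry. `riboseep` implements the
computational core of such a combined workflow for bacteria with
multi-replicon genomes (a chromosome plus megaplasmids, as in
alphaproteobacterial symbionts):

1. strand-aware coverage tracks from aligned Ribo-seq/RNA-seq reads, with
   per-million ("mil") and minimum-library ("min") normalization;
2. per-feature RPKM and translation efficiency (TE), summarized by
   transcript class;
3. metagene diagnostics of the translation-initiation signature;
4. a translation-filter cascade for annotated sORFs and novel ORF
   candidates, plus quantitative proxies for visual curation;
5. hierarchical integration of multiple annotation sources into
   stop-codon-anchored proteoform clusters, and protease-specific, minimally
   redundant proteogenomic search databases;
6. peptide ambiguity classification and tiered PSM-based protein
   acceptance.

A deterministic simulator generates genomes, reads, candidate tables and
PSM tables with known ground truth, so the whole pipeline is testable end
to end.

## Quantification model

Coverage tracks support four read-assignment modes. `global` increments
every covered position; `five_prime`/`three_prime` increment only the
biological read end (these are the modes used for metagene profiles);
`centered` trims `k` nt (default 5) from both read ends before
accumulation — the centering convention is ours, since "centered" full-read
mapping is named but not defined by the upstream tooling, and `k` is
exposed in the interface. Multi-mapped reads are assumed removed upstream.

Per feature and replicate,

* RPKM = count × 10⁹ / (length~nt~ × total mapped reads),
* TE = RPKM~Ribo~ / RPKM~RNA~, defined only where the RNA RPKM is positive,
* mean TE = arithmetic mean of the defined replicate TEs.

Counting uses a permissive ≥ 1 nt same-strand overlap rule, so one read may
count toward several overlapping features; fractional assignment was
rejected for reproducibility. Ribo/RNA replicates are paired by an explicit
pairing table, never by sample-name inference. Undefined TEs propagate as
`NA` and are excluded (and counted) in class summaries — never silently
zeroed.

## Translation calls

Annotated sORFs are called translated when mean TE ≥ 0.5 and both the
RNA-seq and the Ribo-seq RPKM are ≥ 10; all boundaries are inclusive. The
RPKM rule for annotated sORFs defaults to the replicate mean; for novel
candidates it is enforced in every replicate, and a DeepRibo-style
prediction score must additionally be strictly greater than −0.5. The
asymmetry (mean vs. per-replicate) follows the stricter treatment novel
candidates receive in practice, and both rules are configurable
(`sorf_thresholds()`).

Visual curation of candidate loci in a genome browser is encoded as four
quantitative flags computed on min-normalized global tracks
(`curation_flags()`):

* **boundary** — fraction of locus Ribo signal inside the ORF extended by
  the ~16 nt initiation/termination protection ≥ 0.8;
* **utr_exclusion** — mean Ribo density in the residual UTR flanks (30 nt
  beyond the protected window) ≤ 0.3 × in-ORF density;
* **evenness** — no single position carries > 50 % of the in-ORF signal and
  the per-codon coefficient of variation is ≤ 2 (a two-part proxy for
  "peaks with plateau" artifacts);
* **signal_ratio** — in-ORF Ribo mean ≥ 1.0 × in-ORF RNA mean.

The constants are declared conventions, exposed in `curation_params()`;
the underlying criteria are inherently visual and our flags are proxies,
not a re-derivation. A candidate passing the cascade alone is
`filtered_pass`; passing all four flags as well upgrades it to
`translated_high_confidence`. Nested candidates sharing a stop codon are
shadow-resolved toward the highest predictor score (ties to the longest).

## Metagene diagnostics

Profiles anchor position 0 at the first nucleotide of the start codon.
Initiating ribosomes protect ~15–16 nt beyond the start codon, so 5'-end
tracks peak at −16 and 3'-end tracks at −16 + L − 1 for footprints of
length L. Each gene's window (default −30..+30) is sum-normalized before
equal-weight averaging, preventing highly expressed genes from dominating;
the normalization scheme upstream tools use is not documented, so this
choice is ours and is stated here. The length-stratified enrichment score —
initiation-window density over body density per footprint length — is a
declared proxy for "initiation enrichment", whose exact published statistic
is not specified. Codon-level (3 nt) periodicity is deliberately out of
scope: bacterial RNase I footprinting does not resolve it.

## Search databases and peptide evidence

All coding features from the configured annotation sources (reference
annotations ranked above ab initio predictions, ranked above in-silico or
Ribo-seq-informed sets) are validated against the genome — a feature
without a genuine stop codon at its end, e.g. a pseudogene fragment, is
rejected and logged — and grouped by (replicon, strand, last base of the
stop codon). Distinct start sites become proteoforms; the composite cluster
identifier lists every source-qualified contributing id. Integration is
idempotent and insensitive to permuting equal-rank sources.

For a protease, the most upstream proteoform contributes its full sequence;
each shorter proteoform contributes its N-terminal stretch through cleavage
site (1 + missed cleavages) downstream of its start. This is exactly
sufficient: every peptide with up to that many missed cleavages that could
distinguish the start is contained in some entry (the test suite proves
completeness by brute-force digestion, and minimality by showing that
trimming one residue from a truncated entry loses a peptide — for children
whose start codon is not an internal ATG of the parent, since an internal
ATG child is indistinguishable from the parent at the peptide level).
Protease dialects: trypsin cleaves after K/R except before P (the standard
convention, declared here since only the LysC rule is fully specified
upstream), LysC after every K, and the no-protease database performs no
truncation at all. Six-frame in-silico ORF prediction emits up to 5
alternative starts per stop (most upstream first) at a 10 aa minimum — a
floor chosen with margin below the smallest products typically detected by
MS (~12 aa).

Peptides are classified against the full proteoform sequences: class 1a
(single proteoform of a single cluster), 2a (proper subset of one
cluster's proteoforms — start-specific evidence), 2b (all proteoforms of
one cluster — gene-level evidence), 3a (several clusters but one identical
protein sequence — duplicated gene copies), otherwise ambiguous. Classes
1a/2a/3a count as unique evidence (2a inclusion is configurable), 2b adds
gene-level PSM support, ambiguous peptides are excluded.

Acceptance tiers: proteins of ≥ 15 kDa require two unique peptides
regardless of category (exactly 15 kDa is placed in this regime, a
documented choice since the published boundary is stated as both "<" and
">"); below 15 kDa, annotated proteins need one unique peptide with ≥ 2
PSMs, ab initio predictions ≥ 3 PSMs, and in-silico/Ribo-seq predictions
≥ 4 PSMs, or 3 PSMs when observed in each of the three replicates. Protein
mass uses average residue masses plus one water. PSM counts are pooled
within a database build. Spectral search and FDR control are upstream of
this package; its inputs are pre-filtered PSM tables.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions all recovery tests run
under: a three-replicon toy genome (120 + 60 + 40 kb standing in for a
chromosome and two megaplasmids), ~40 translated CDS with UTRs, one operon
whose first intergenic gaps are 14 and 12 nt, 20 standalone sORFs of
10–70 aa (25 % leaderless, half annotated and half novel), upstream ORFs
inside 5'-UTRs, antisense sORFs opposite host 3'-UTRs, untranslated sRNAs
carrying decoy ORFs, housekeeping RNAs, one duplicated sORF gene pair, two
replicates and 2 × 10⁵ reads per library. Footprints are 27–33 nt with the
mode at 30; 5' ends pile up at −16 and 3' ends at +16 around the ORF, with
the strongest initiation pile-up given to 32 nt footprints; read counts are
Poisson around expectations proportional to TE × transcript abundance; RNA
fragments (25–40 nt) tile whole transcripts. Background Ribo-seq noise
defaults to 0 and is exposed as a rate parameter for specificity tests.
Reads are emitted pre-aligned: mapping, sequencing error and rRNA
contamination are out of scope.

Raw TE levels are drawn log-normally (median ≈ 1.4, truncated to 0.8–3) and
converted to the RPKM-ratio scale before they are recorded as truth: the
RPKM-ratio TE is compositional (it depends on what else is in the
libraries), so the recorded planted value is the exact estimand of the
downstream quantifier, computed from the expected library compositions and
the exact per-feature probability that an RNA fragment overlaps the ORF.
Without this, "planted TE" would be systematically mis-scaled for short
transcripts and recovery tests would test the calibration error rather than
the pipeline.

Consequences worth knowing: operon genes cross-count a small number of
neighbor pile-up reads across their 12–14 nt gaps (the permissive overlap
rule, faithfully reproduced), so their TE estimates are the least accurate;
and with planted TE straddling 1, the signal-ratio curation flag rejects a
realistic fraction of genuinely translated low-TE sORFs, exactly as visual
curation does. Recovery tests therefore measure the cascade
(`filtered_pass`), with curation reported separately. Passing on this
simulator shows the machinery is correct under its assumptions; it does not
show robustness to mapping artifacts, rRNA contamination, codon-level
pausing or non-Poisson overdispersion, none of which are modelled.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; GFF3 I/O converts at the
boundary, and the conversion is an exact bijection. Stop codons are inside
CDS/sORF intervals but excluded from `aa_length`. Features wrapping a
circular replicon's origin are rejected. Zero-total libraries cannot be
normalized (error, not NaN); zero in-ORF Ribo coverage sets all curation
flags false; empty feature classes are absent from summaries rather than
zero. All simulator randomness derives from the single configured seed, so
every output is reproducible byte for byte.

## Problem sizes used by the test suite

The default simulation (~2 × 10⁵ reads per sample, two replicates) drives
the end-to-end recovery tests; unit tests use a smaller genome (40 + 20 kb)
and 6 × 10⁴ reads. Database oracles run on 60 kb of random sequence
(~1 400 clusters, 200 multi-proteoform clusters checked by brute-force
digestion). These sizes give stable statistics for every property tested
while keeping the full suite fast on a single CPU.

## A worked example

```{r example, eval = FALSE}
library(riboseep)

cfg <- sim_config(seed = 1)
res <- run_pipeline("riboseep_demo", cfg)

# initiation signature
peak <- res$metagene$positions[which.max(res$metagene$mean_profile)]
peak          # -16

# per-class translation efficiency
res$te_summary

# cascade recovery against the planted truth
recovery_stats(res$genome, res$novel_calls)
```

See the README for the exact numbers this prints and what they mean.
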