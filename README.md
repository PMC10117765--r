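# riboseep

Mapping a bacterial translatome from paired ribosome profiling (Ribo-seq)
and RNA-seq data, and discovering small ORF-encoded proteins (SEPs) by
combining translation evidence with integrated proteogenomic search
databases.

## Who this is for

Groups running Ribo-seq in bacteria — particularly species with
multi-replicon genomes (a chromosome plus megaplasmids) — who want to go
from aligned reads, candidate-ORF score tables and filtered
peptide-spectrum-match (PSM) tables to a curated list of translated small
ORFs (≤ 70 aa) and MS-confirmed proteins. Read trimming/mapping, the ORF
predictors themselves (DeepRibo/REPARATION-style tools) and spectral
search/FDR control are upstream; this package consumes their outputs.

## What it computes

**Coverage and quantification.** Strand-aware coverage tracks under four
read-assignment modes (full-read `global`, trimmed `centered`, and
single-nucleotide `five_prime`/`three_prime`), with per-million ("mil") and
minimum-library ("min") normalization. Per feature and replicate:

    RPKM = count x 1e9 / (length_nt x total mapped reads)
    TE   = RPKM_Ribo / RPKM_RNA        (defined where RPKM_RNA > 0)

**Metagene diagnostics.** Ribosome density around start codons (+1 = first
nt of the start codon): initiating ribosomes protect ~16 nt upstream, so
5'-end tracks peak at −16 and 3'-end tracks at −16 + L − 1 for footprints
of length L; an enrichment score stratified by footprint length (27–33 nt)
identifies which length carries the strongest initiation signal.

**Translation calls.** Annotated sORFs pass when mean TE ≥ 0.5 and RNA-seq
and Ribo-seq RPKM ≥ 10 (inclusive boundaries); novel candidates must meet
the RPKM rule in every replicate and carry a predictor score > −0.5
(strict). Four quantitative curation flags (coverage within boundaries,
UTR exclusion, evenness, Ribo/RNA signal ratio) encode the visual curation
criteria; genomic contexts (5'/3'-UTR, sRNA-hosted, operon-internal,
antisense, intergenic) are classified by precedence rules.

**Proteogenomic databases.** Coding features from ranked annotation
sources are validated against the genome and clustered by shared stop
codon; distinct start sites become proteoforms. Per protease (trypsin,
LysC, or none), the most upstream proteoform is emitted in full and each
shorter one only as the N-terminal stretch through cleavage site
(1 + missed cleavages) — a large but minimally redundant search database.
A six-frame in-silico ORF scan with alternative starts builds the standard
database; a Ribo-seq-informed candidate set builds the much smaller custom
database.

**Peptide evidence.** Peptides are classified (1a unique / 2a
start-specific / 2b gene-level / 3a identical gene copies / ambiguous) and
proteins accepted by tier: ≥ 15 kDa needs two unique peptides; < 15 kDa
needs one unique peptide with ≥ 2 PSMs (annotated), ≥ 3 PSMs (ab initio),
or ≥ 4 PSMs (in-silico/Ribo-seq; 3 PSMs suffice when seen in each of three
replicates).

**Simulator.** `sim_config()`/`make_genome()`/`simulate_reads()`/
`simulate_psms()` generate a deterministic toy genome with planted
transcripts (CDS with UTRs, an operon with 14/12 nt gaps, leaderless
sORFs, uORFs, antisense sORFs, untranslated sRNAs with decoy ORFs,
duplicated gene copies), footprints with the −16/+16 pile-up signature,
and PSM tables — with a ground-truth table for recovery testing.

## Worked example

```r
library(riboseep)

cfg <- sim_config(seed = 1)
res <- run_pipeline("riboseep_demo", cfg)

res$metagene$positions[which.max(res$metagene$mean_profile)]
#> [1] -16

res$te_summary
#>   feature_class   mean_te n_features n_excluded
#> 1           CDS 1.0635205         43          0
#> 2         hkRNA 0.0000000          6          0
#> 3          sORF 0.7706976         40          0
#> 4          sRNA 0.0000000         10          0

recovery_stats(res$genome, res$novel_calls)
#> $sensitivity
#> [1] 1
#> $false_admission
#> [1] 0

table(res$novel_calls$verdict)
#>                       fail              filtered_pass
#>                         10                         12
#> translated_high_confidence
#>                          8
```

Reading this: the pooled 5'-end metagene peaks at −16 nt, the initiation
signature of footprints protected by ribosomes poised on start codons.
Mean TE is ~1 for translated CDS and exactly 0 for untranslated sRNA and
housekeeping-RNA classes. Every planted translated novel sORF passes the
TE/RPKM/score cascade (sensitivity 1) and none of the untranslated decoy
ORFs is admitted (false admission 0); the 10 failures are exactly the
decoys. Of the 20 true candidates, 8 additionally pass all four curation
flags — the stricter high-confidence tier rejects genuinely translated but
low-TE sORFs, just as visual curation does.

Every stage's table (quantification, class TE summary, metagene profile,
calls, custom database FASTA/GFF, acceptance master table) is written to
the output directory along with a manifest (seed, configuration echo,
output checksums).

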