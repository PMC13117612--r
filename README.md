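# lncpair

Cis-regulatory lncRNA–protein-coding-gene pair analysis for
single-nucleus transcriptomes.

Long noncoding RNAs (lncRNAs) are frequently transcribed next to, or on
the opposite strand of, protein-coding genes (PCGs), and many of them
regulate their genomic neighbour in *cis*. In single-nucleus RNA-seq of
a differentiating tissue — the motivating system is the human placental
trophoblast lineage, with cytotrophoblast (CTB), syncytiotrophoblast
(STB) and extravillous trophoblast (EVT) cells at early and late
gestation — candidate cis-regulatory pairs show up as proximal
lncRNA–PCG loci whose expression is correlated across nuclei and
co-varies along differentiation trajectories. `lncpair` implements that
analysis end to end, together with a fully seeded synthetic-data
generator so every stage can be validated against known ground truth
without any external download.

The package is tidyverse-shaped: user-facing functions take a data
frame (or a `cell_matrix` container) first and return tibbles, results
have `autoplot()` methods, and fitted objects have `tidy()`/`glance()`
methods.

## What it computes

**Genomic configuration of a pair.** Every same-chromosome lncRNA–PCG
pair whose spans lie within a window *w* (default 5,000 bp; overlap
counts as gap 0) is classified into one of six configurations:

| label | meaning |
|-------|---------|
| XH | antisense head-to-head (divergent promoters) |
| XT | antisense tail-to-tail (convergent 3' ends) |
| XI | intronic antisense (lncRNA inside the PCG span, no exon overlap) |
| XO | exonic overlapping (≥ 1 bp of antisense exon–exon overlap) |
| SU | sense upstream (same strand, lncRNA TSS upstream of the PCG TSS) |
| SD | sense downstream |

Antisense pairs are resolved by the priority cascade XO → XI → XH/XT,
where XH vs XT compares the TSS–TSS and TES–TES distances (tie → XH).

**Single-nucleus QC** with explicit boundary semantics: keep a nucleus
iff 3,500 ≤ UMI ≤ 50,000, 1,500 ≤ detected genes ≤ 5,000, mitochondrial
fraction < 5% and doublet score < 0.5 (all configurable via
`qc_thresholds()`).

**Marker specificity** per gene and group contrast: detection
percentages (pct.1, pct.2), Δ percentage = pct.1 − pct.2, log2 fold
change of linear-scale means, a two-sided Wilcoxon rank-sum p-value
(exact for pooled n ≤ 12 without ties) and Benjamini–Hochberg q.

**Pair co-expression**: counts-per-10k log normalisation, a
Markov-affinity diffusion operator over cells (kNN Gaussian kernel,
k = 15, t = 3 smoothing steps on 30 PCs) for dropout imputation, then a
Pearson `cor.test` per pair with one BH family, summarised per
configuration.

**Trajectory co-dynamics**: ordering genes per lineage transition
(|log2FC| ≥ 2, adjusted p < 0.05, mean expression in the top 20% of
tested genes; PCGs and lncRNAs alike), equal-occupancy pseudotime
binning (20 bins), Pearson correlation of the two binned profiles, and
a high-confidence call when both members are ordering genes and the
trajectory correlation reaches r ≥ 0.5 at BH q ≤ 0.05.

**RNA velocity** under the steady-state model: genes filtered at
min_shared_counts = 20 per layer, per-gene degradation/splicing ratio γ
fitted as the origin-constrained slope of unspliced on spliced over the
extreme 5% quantiles, velocity v = u − γs, and the per-cell **velocity
length** (L2 norm of the velocity vector across genes) summarised per
cell group against transcript abundance.

**Synthetic data**: `sim_config()` + `simulate_annotation()`,
`simulate_counts()`, `simulate_kinetics()`, `simulate_pseudotime()`
generate a GTF with planted pair configurations in exact proportions,
negative-binomial counts over the six trophoblast groups with a planted
lncRNA UMI share (3.47%), copula-planted pair correlations, planned QC
failures and doublets, spliced/unspliced layers from the two-state
transcription model du/dt = α − βu, ds/dt = βu − γs, and
lineage-monotone pseudotime — everything recorded in truth tables.

## Worked example

```r
library(lncpair)

cfg <- sim_config(seed = 11)            # the default synthetic study
fx  <- simulate_fixture(cfg, "fixture") # GTF + MTX + metadata on disk

run <- run_pipeline(pipeline_config(
  gtf = fx$paths$gtf, counts_dir = fx$paths$counts,
  cell_meta = fx$paths$cell_meta,
  spliced_dir = fx$paths$spliced, unspliced_dir = fx$paths$unspliced,
  out_dir = "run1", qc = cfg$qc, seed = 11))

configuration_frequencies(run$pairs)
dplyr::filter(configuration_cor_summary(run$correlations),
              cell_group == "all", basis == "imputed")
sum(run$calls$called)
```

On the default fixture (six groups × 500 nuclei, ~1,500 genes) this
prints a configuration spectrum of 34% XH, 20% XT, 16% XI, 2% XO, 14%
SU, 14% SD (the planted proportions, recovered exactly); per-category
median imputed pair correlations between 0.49 and 0.90 — positive for
all six configurations, the signature of widespread positive
cis-co-expression; and 21 high-confidence trajectory calls, exactly the
planted regulatory pairs. `markers_*.tsv`, `velocity_summary.tsv` and
the run manifest land in `run1/`; rerunning with the same seed
reproduces every file byte for byte.

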