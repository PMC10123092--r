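# riboselect

Analysis of **selective ribosome footprinting** experiments in R. In these
experiments, ribosomes bound by a factor of interest (an initiation factor
or another ribosome-associated protein) are immunoprecipitated and their
protected mRNA fragments sequenced alongside a matched total-ribosome
library, for both scanning (40S) and elongating (80S) ribosomes. The
selective/total footprint ratio along a transcript then reports where the
factor engages the ribosome. The package is aimed at computational
biologists working with 40S/80S footprint libraries who want the core
statistics of such a study as tested, reusable functions rather than
one-off scripts.

## What it computes

**Co-translational assembly score.** For each gene, the CDS is scaled to
0–100% and split into `n_bins` bins; per bin the ratio of depth-normalized
selective to total 80S footprints is computed. The ratio profile
*r*<sub>1..n</sub> is fit with a one-breakpoint step function by exhaustive
least squares: for every breakpoint *b* the means of the two sides are
taken and the breakpoint minimizing

&nbsp;&nbsp;SSE(b) = Σ<sub>i&lt;b</sub> (r<sub>i</sub> − μ<sub>L</sub>)² +
Σ<sub>i≥b</sub> (r<sub>i</sub> − μ<sub>R</sub>)²

is selected. The score is μ<sub>R</sub> − μ<sub>L</sub>: a large positive
score marks a sudden increase in factor-bound ribosomes part-way through
the CDS, the signature of the factor engaging the nascent chain once its
binding site has emerged. `fit_step()` is the direct O(n²) reference and
`fit_step_fast()` an exact O(n) prefix-sum version; both return a classed
model object with `print`, `summary`, `coef`, `predict`, `residuals`,
`simulate` and `plot` methods.

Around that core:

- **uORF annotation** — AUG-initiated upstream ORF detection in 5′UTRs
  (with optional near-cognate starts), overlapping-ORF (oORF)
  classification, translated-uORF calling (≥ 1 total-80S footprint), and
  the accompanying statistics: Mann–Whitney uORF-count enrichment between
  gene sets and a binomial test for gene-set overlap.
- **Metagene profiles** — footprint signal around mORF/uORF start and stop
  codons, with per-million library-depth normalization for 80S tracks,
  scanning-ribosome equalization (80–100 nt upstream of the start) for 40S
  tracks, and sliding-window smoothing to remove triplet periodicity.
- **Selectivity and translation efficiency** — per-gene selective/total
  40S binding ratios in 5′UTRs, top/bottom binding deciles,
  Kruskal–Wallis + Dunn comparison across uORF categories, per-gene
  translation efficiency (CDS 80S footprints / mRNA) and its log2 change
  between conditions, and the Spearman correlation between binding and
  ΔTE.
- **Synthetic data** — a seeded generator (`simulate_transcriptome()`,
  `simulate_footprints()`) producing transcriptomes with planted uORFs and
  footprint libraries from an explicit generative model (leaky-scanning
  43S stream, Poisson counts, binomial selective-IP thinning with a
  capture-probability step on interactor CDSs), so every analysis stage is
  testable without external sequencing data.
- **Pipeline** — `run_pipeline()` drives simulate → uORF → score →
  metagene → selectivity from one YAML/list config and writes a manifest
  with per-file checksums for reproducible runs.

Tracks and annotation use standard formats (GFF3/BED12, FASTA, bedGraph in
transcript coordinates, TSV); all coordinates are 0-based half-open in
transcript space.

## Worked example

Simulate 100 genes, a few of which carry a selective-capture step
(0.05 → 0.5) at 40% of the CDS, and rank genes by assembly score:

```r
library(riboselect)

cfg <- sim_config(n_transcripts = 100, elong_density = 4,
                  ip_base_rate = 0.05, ip_step_rate = 0.5,
                  interactor_fraction = 0.05, seed = 42)
sim    <- simulate_transcriptome(cfg)
libs   <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
scores <- score_genes(libs$selective80S, libs$total80S, sim$transcripts)
head(scores[, c("gene_id", "score", "breakpoint_nt", "mean_left", "mean_right")], 5)
#>   gene_id score breakpoint_nt mean_left mean_right
#> 1  tx0067  7.33           134     0.659       7.99
#> 2  tx0028  6.99           443     0.608       7.60
#> 3  tx0027  6.78           470     0.682       7.46
#> 4  tx0083  6.74           180     1.064       7.80
#> 5  tx0059  6.73           334     0.820       7.55
```

All five top-ranked genes are true interactors in the simulation's truth
table, and the reported breakpoints (nt into the CDS) match the planted
ones (tx0067: 134, tx0028: 443, ...). The score ≈ 7 reflects the ~10-fold
capture increase after the breakpoint relative to a pre-breakpoint ratio
near 0.7. Inspecting one fit directly:

```r
tr   <- sim$transcripts[[scores$gene_id[1]]]
prof <- compute_ratio_profile(libs$selective80S, libs$total80S, tr)
fit_step_fast(prof)
#> One-breakpoint step fit
#>   breakpoint: 40 of 100 bins (left [0,40), right [40,100))
#>   means: left 0.6594, right 7.985
#>   assembly score (right - left): 7.326   SSE: 485.3
```

The breakpoint at bin 40 of 100 corresponds to the planted step at 40% of
the CDS.

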