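---
title: "Models and methods behind riboselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboselect)
```

This vignette explains the statistical models the package implements, the
generative model behind its synthetic data, the tunable parameters and
their defaults, and the numerical and design choices a user should know
about before trusting the output.

## The experimental quantity being modelled

Selective ribosome footprinting immunoprecipitates ribosomes bound by a
factor of interest and sequences their protected fragments, alongside a
matched total-ribosome library, separately for scanning 40S and
elongating 80S ribosomes. After depth normalization, the selective/total
count ratio along a transcript estimates the probability that a ribosome
at that position carries the factor. Two spatial patterns carry the
biology:

* a **step increase** of the selective/total 80S ratio part-way through a
  CDS indicates that the factor starts to engage ribosomes only after a
  defined point of elongation — the signature of co-translational
  engagement of the nascent chain;
* the **level** of the selective/total 40S ratio over a 5′UTR measures
  how selectively the factor associates with scanning ribosomes on that
  mRNA.

## The one-breakpoint step fit

For a gene with CDS positions scaled to 0–100% and partitioned into
`n_bins` near-equal nucleotide bins, the per-bin ratio is

$$r_k = \frac{s_k / S + c}{t_k / T + c},$$

where $s_k, t_k$ are selective and total counts in bin $k$, $S, T$ the
library sizes (counts are expressed per million reads), and $c$ a
pseudocount. The profile $r_{1..n}$ is fit by exhaustive least squares
over all breakpoints $b \in \{1, \dots, n-1\}$: each side of the
candidate breakpoint is summarized by its mean, the breakpoint minimizing
the total sum of squared residuals is selected, and the **assembly
score** is the right mean minus the left mean. Both segments are always
non-empty, and ties in SSE resolve to the smallest breakpoint so results
are deterministic.

`fit_step()` implements this literally, recomputing means per candidate
(O(n²)); `fit_step_fast()` computes identical results from running sums
of $x$ and $x^2$ in O(n). The two are checked against each other on
thousands of random profiles in the test suite. Floating-point SSE ties
are resolved with an absolute tolerance that scales with the profile's
energy (`1e-10 * (1 + sum(x^2))`), so exact ties (constant or
perfect-step profiles) pick the smallest breakpoint in both
implementations.

Properties the tests verify: translation invariance (adding a constant
moves the means, not the breakpoint or score), positive-scale
equivariance (the score scales with the profile), and exact recovery of
noise-free steps.

### Parameters

* `n_bins` (default **100**): the CDS is scaled to 0–100%, so one bin per
  percentage point. CDSs shorter than `n_bins` nucleotides fall back to
  per-nucleotide bins with a warning.
* `pseudocount` (default **0.5**, in reads-per-million units): added
  symmetrically to the numerator and denominator, so a bin with no
  coverage in either library has ratio 1 (no evidence of enrichment or
  depletion) rather than being dropped — bin indices stay comparable
  across genes. The flat case is unbiased: equal tracks give ratio 1 at
  any pseudocount.
* `min_counts` (default **32** total-80S CDS counts in every compared
  library): the detected-gene floor. Ratio statistics on fewer reads are
  dominated by shot noise. The threshold is configuration, not a claim
  about any particular dataset.

A practical caveat established during development: when per-bin total
counts are low (roughly below 20), the tail bins of the exhaustive search
(segments of a single bin) can produce extreme ratio outliers — the ratio
of two small Poisson counts — which inflate the null distribution of
scores. Scores from shallow genes should be treated with caution; the
detection floor exists for exactly this reason.

## uORF detection and classification

The 5′UTR is scanned 5′→3′ for ATG (optionally also the nine
single-mismatch near-cognate codons, off by default since near-cognate
initiation calls need orthogonal evidence). Each start is extended in
frame to the first stop codon. If the stop ends at or before the mORF
start, the ORF is a uORF; otherwise — including a stop codon straddling
the mORF start — it is an overlapping ORF (oORF), because a ribosome
terminating past the mORF start cannot have initiated the mORF.
Overlapping and nested uORFs are all reported, without masking, since
downstream statistics count uORFs per 5′UTR. The finder is validated
against a brute-force enumeration over all (position, frame) pairs.

A uORF is **translated** when it contains at least `min_reads` (default
**1**) total-80S footprints — a deliberately low-stringency rule, exposed
as configuration. Transcripts then fall into three categories: no uORF,
uORFs but none translated, and at least one translated uORF; the three
categories partition the transcript set.

Two set-level statistics accompany the annotation: a two-sided
Mann–Whitney test comparing uORF counts between a target and a background
gene set, and an upper-tail binomial test for the overlap of two gene
sets in a universe of size $N$ ($X \sim \mathrm{Bin}(|A|, |B|/N)$,
$p = P(X \ge \text{observed})$).

## Metagene profiles

`collect_anchored()` gathers per-nucleotide counts around an anchor codon
(mORF or uORF start/stop; offset 0 is the first nucleotide of the codon)
into an anchors × offsets matrix. Offsets outside a transcript are
masked, not zero-filled, and aggregation divides each offset by the
number of contributing anchors — otherwise short 5′UTRs would drag the
upstream flank toward zero. uORF anchors keep only AUG-initiated,
translated uORFs with at least 80 nt between the uORF stop and the mORF
start, so that uORF-stop signal does not bleed into main-start signal.

Normalizations mirror how such figures are drawn: 80S profiles are
divided by library size (per million reads); 40S profiles are rescaled so
every library has the same summed signal in the scanning window upstream
of the start codon (default offsets −100..−80, i.e. 80–100 nt upstream),
putting libraries on a common "scanning ribosomes approaching the start"
scale. Smoothing is a centred moving average whose window shrinks
symmetrically at the edges; a 3-nt window removes the triplet periodicity
of elongating ribosomes. Default windows are −100..+200 nt around start
anchors and −200..+100 nt around stop anchors — wide enough to show the
approach and the body, but configuration rather than a claim.

## Binding selectivity and translation efficiency

Per gene, the **binding ratio** is the depth-normalized selective/total
40S count ratio over the 5′UTR (same pseudocount policy as above, one
shared configuration key for comparability). Genes are ranked and the top
and bottom `floor(fraction * n)` (default fraction 0.1) labelled, with
ties broken by gene id for determinism. Binding across the three uORF
categories is compared with a Kruskal–Wallis omnibus test followed by
Dunn's rank-based pairwise z tests with the standard tie correction;
multiplicity adjustment is Bonferroni over the three pairs — conservative
and simple, appropriate for three comparisons. Fully tied data are
reported as statistic 0 rather than 0/0.

**Translation efficiency** is the depth-normalized CDS 80S count divided
by the depth-normalized mRNA count, per condition; the package reports
`log2(TE_treated / TE_control)` and leaves formal differential
significance to dedicated differential-translation tools, which model the
overdispersion of replicated count data properly. TE is invariant to
scaling any single library, which the tests assert. The binding–ΔTE
relationship is summarized by Spearman's rank correlation: ratio
statistics are heavy-tailed, so a rank-based estimator is the safer
default.

## The synthetic-data generator

The generator exists so that every analysis stage has inputs with known
truth. Its generative model, per transcript:

1. A single 43S preinitiation stream enters at the cap with unit flux. At
   each uORF start codon, a fraction equal to that uORF's initiation
   probability (drawn from `kozak_strengths`) initiates and leaves the
   stream; the remainder leaky-scans onward. At the mORF start a fraction
   `morf_init` initiates. Reinitiation after uORF termination is a single
   per-uORF probability, default 0 — the analyses need uORF-dependent
   mORF repression, not a full reinitiation model.
2. 40S counts per 5′UTR nucleotide are Poisson with mean `scan_density`
   times the surviving stream at that position; 80S counts per ORF
   nucleotide are Poisson with mean `elong_density` times the flux that
   initiated on that ORF.
3. Selective libraries are per-position binomial thinnings of the totals.
   The capture probability is `ip_base` everywhere except downstream of
   the breakpoint on interactor CDSs (80S only), where it is `ip_step`.
4. The knockdown condition multiplies every uORF initiation probability
   by `depletion_leak_shift` (capped at 1): a factor that promotes leaky
   scanning, when depleted, increases uORF initiation and so drains flux
   from the mORF.

Sequences carry literal ATG/stop trinucleotides at every annotated
position; the 5′UTR background is scrubbed of spurious ATGs so annotation
and sequence agree, while uORF bodies use sense codons only. Randomness
derives one substream per transcript from the run seed, so identical
configs are bit-identical regardless of evaluation order.

Default condition choices: 200 transcripts, 5′UTRs 120–300 nt, CDSs
300–1500 nt, one expected uORF per 5′UTR, Kozak strengths
{0.05, 0.15, 0.4} (leaky scanning dominant), `morf_init` 0.8,
`scan_density` 0.5 and `elong_density` 1 — giving tens of 40S reads per
5′UTR and a few hundred 80S reads per CDS, the coverage regime of
well-detected genes in a deeply sequenced footprinting library while
staying desk-scale; capture rates 0.1 → 0.5 with breakpoint at 40% of the
CDS on 10% of transcripts; `depletion_leak_shift` 2; mRNA counts Poisson
with mean 200, equal across conditions (the simulated depletion acts on
translation, not transcript abundance). The relative 40S/80S depths are a
modelling choice made once so that both metagene types are non-sparse.

What the generator does **not** emulate: codon usage or GC structure,
rRNA contamination, alignment artefacts and multimapping, read-length
biology beyond uniform draws within the gel size-selection windows
(25–35 nt for 80S, 20–80 nt for 40S), positional pausing, biological
replicate variability beyond Poisson noise, and transcript isoforms.
Tests passing on these data therefore demonstrate correctness of the
statistics under the stated model, not robustness to every artefact of
real libraries.

## Numerical choices and degenerate inputs

* Coordinates are uniformly 0-based half-open in transcript space; every
  interval operation plus its complement partitions the transcript total
  (property-tested).
* Step-fit tie-break: smallest breakpoint, with the energy-scaled
  tolerance above.
* Zero-coverage bins are imputed at the pseudocount ratio (1), not
  dropped; a transcript with no total coverage in any bin is flagged
  unusable instead of producing NaNs. With pseudocount 0, 0/0 bins are
  reported as 0.
* Read-position assignment is the 5′ end plus a fixed species-specific
  offset (default 0), exposed as configuration because P-site calibration
  is a property of the protocol, not of this analysis.
* Replicates are handled by computing scores per replicate and averaging,
  matching how paired replicate libraries are usually summarized.
* Smoothing windows shrink symmetrically at profile edges so no offsets
  are lost; window 1 is the identity.
* The detected-gene rule, the translated-uORF read threshold, the
  intercistronic floor, all windows, bins and pseudocounts are single
  configuration keys with the defaults stated above.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic data:
1000 random profiles for the step-fit equivalence check, 200 simulations
for breakpoint recovery at ~25 total reads per bin, 20 simulations of 200
genes for the planted-interactor ranking (at `elong_density` 4, the same
≥ 20 reads/bin regime as the recovery check), 500 random 5′UTRs for the
uORF oracle, 1000 null replicates for the type-I calibration of the
rank-sum and Kruskal–Wallis tests, 150 transcripts with long 5′UTRs for
the knockdown metagenes, and 1000 genes for the binding–ΔTE correlations.
These sizes make the whole suite run in about a minute while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The step model fits exactly one breakpoint; factors that engage and
  release (two steps) or engage gradually are summarized by a single
  step, and the score understates them. Multi-breakpoint segmentation is
  deliberately out of scope.
* The score carries no significance estimate; it is a ranking statistic.
  At low coverage the null distribution of scores widens markedly (see
  the caveat above).
* Genome-space input (multi-exon projection, strand handling) is out of
  scope: tracks are transcript-coordinate by construction.
* The uORF statistics assume one principal transcript per gene; isoform
  collapsing is the caller's responsibility.
* Differential TE significance is delegated to dedicated tools; the
  log2 ratios reported here are descriptive.
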