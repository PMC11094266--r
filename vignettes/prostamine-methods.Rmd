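---
title: "Mining subtype-specific co-alterations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining subtype-specific co-alterations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostamine)
```

## The data model

`prostamine` operates on a harmonized multi-cohort container holding four
layers keyed by gene symbol and sample id:

* **alterations** — boolean Loss and Gain matrices derived from discretized
  GISTIC-style copy-number calls plus deleterious-mutation flags. A Gain is
  any call > 0 and a Loss any call < 0 *or* a deleterious single-base
  substitution; magnitude (±1 vs ±2) is deliberately ignored because only the
  direction of the lesion enters the model. Damage predictions
  (SIFT/PolyPhen-2 style) are consumed as a precomputed boolean, never
  computed here.
* **expression** — per-study z-scores passed through untouched. Whether a
  study z-scored primaries and metastases jointly or separately is a property
  of the upstream harmonization; re-normalizing here would silently change
  the transcriptomic filter, so we do not.
* **clinical** — sample type (primary/metastatic), Gleason grade, T/N stage,
  and progression-free survival (PFS) time/event. Metastatic samples may
  lack grade and PFS.
* **annotation** — BED-like coordinates (0-based, half-open on disk) giving
  each gene an order index along its chromosome; hotspot spans are reported
  1-based inclusive for human-readable labels.

Merging cohorts intersects gene sets and concatenates samples; nothing else
is recomputed. Two conventions fill gaps the inputs cannot resolve: a cell
with a positive copy-number call *and* a deleterious mutation keeps the
copy-number direction (Gain) with a warning, configurable to "neither"; and
a missing copy-number cell yields no call while the sample still counts in
frequency denominators, keeping frequency = altered/total exact.

## Statistical primitives

All stages share one small kit: Fisher's exact test (exact hypergeometric,
computed from the point masses so thousands of gene tables vectorise; the
one-sided "greater" tail is used wherever the hypothesis is *enrichment*,
the two-sided test where it is association, i.e. mutual exclusivity versus
co-occurrence), the pooled-variance two-sample t-test (Student's form rather
than Welch, matching the expression model of a shift between altered and
unaltered samples), Benjamini–Hochberg step-up FDR, the two-group logrank
test, and a univariate Cox fit with Breslow tie handling whose hazard ratio
is reported but never used for filtering. Degenerate inputs are outcomes,
not errors: an all-zero Fisher table, a zero-variance t-test with equal
means, and an event-free logrank all return p = 1 with a degenerate flag; a
monotone Cox partial likelihood is flagged non-converged with a signed
infinite hazard-ratio sentinel.

Median stratification assigns values strictly above the median to the upper
stratum and everything else (including ties) to the lower one — a
deterministic rule that preserves "upper = strictly above median" — and
refuses to stratify fewer than four values or a constant vector.

## The mining cascade

Given a subtype (gene + direction), samples split into ST (carrying the
alteration), WT (diploid for the gene), and an excluded remainder (altered
only in the opposite direction, or missing clinical typing); each of the
four ST/WT × primary/metastatic groups must be non-empty.

**Genomic step.** For every other gene × direction, the observed frequency
differences `f(ST primary) − f(WT primary)` and
`f(ST met) − f(ST primary)` are compared to the thresholds `primary_diff`
and `met_diff` (arithmetic differences, matching the "co-alteration rate
difference" control of the interactive tool, not ratios). One-sided Fisher
enrichment tests support each contrast at BH FDR ≤ `coalt_fdr`. The BH
families mirror the sequential capture: the primary family contains the
gene×directions passing the primary frequency filter, and the metastatic
family those that additionally passed primary FDR and the metastatic
frequency filter. Correcting over all ~2·n\_genes never-captured tests
instead would let the family size, not the evidence, decide the metastatic
contrast at realistic cohort sizes. The subtype gene itself is never a
candidate; genes on the same chromosome are *not* auto-excluded, but every
hit carries its genomic distance to the subtype gene so segment-linkage
artifacts are visible.

**Transcriptomic step.** Within ST tumors only, each candidate's expression
effect is the difference of mean z-scores between altered and unaltered
samples, separately for primaries and metastases (a difference of means,
not a ratio — z-scores can be negative, so fold changes are ill-defined).
Losses must be down and Gains up in *both* compartments; survivors need
BH FDR ≤ `dge_fdr` per compartment, with the family being the concordant
survivors. Candidates with fewer than two altered or two unaltered
expressing samples in either compartment are removed with an explicit
reason.

**Clinical step.** ST and WT primaries are median-stratified by the
candidate's expression; the adverse stratum is the lower one for Losses and
the upper one for Gains. A hit must show (a) enrichment of Gleason ≥
`gleason_cutoff` in the adverse ST stratum — a direction requirement only by
default, since only the survival filter carries stated thresholds; an
optional `gleason_fdr` tightens it — (b) worse PFS in the adverse ST stratum
(the direction that is concordant with the metastatic enrichment) at logrank
p ≤ `survival_p_st`, and (c) *no* PFS difference under the same
stratification in WT primaries, p ≥ `survival_p_wt`. The band
`survival_p_st < p < survival_p_wt` excludes candidates from neither side;
the window is applied literally rather than collapsed to one threshold. WT samples lacking
expression are dropped from the WT test only.

**Scoring.** Hits are ranked by primary difference (descending), metastatic
difference (descending) and ST logrank p (ascending), ties sharing the
minimum rank order. With `NR = 1 − rank/N`, the score is
`0.3·NR_primary + 0.3·NR_met + 0.4·NR_surv`, bounded by `1 − 1/N`; a single
hit therefore scores 0, which is a property of the normalization, not a
judgement of the hit.

### Parameters

| parameter | default | strict profile | meaning |
|---|---|---|---|
| `primary_diff` | 0.02 | 0.05 | minimum ST−WT primary frequency difference |
| `met_diff` | 0.02 | 0.05 | minimum ST-met − ST-primary difference |
| `coalt_fdr` | 0.05 | 0.05 | BH bound for both enrichment contrasts |
| `dge_fdr` | 0.20 | 0.20 | BH bound per expression compartment |
| `survival_p_st` | 0.20 | 0.05 | max logrank p in ST tumors |
| `survival_p_wt` | 0.30 | 0.30 | min logrank p in WT tumors |
| `gleason_cutoff` | 8 | 8 | high-grade threshold |

The 0.02 baseline is the permissive default of the interactive workflow;
`prostamine_profile()` is the stricter parameterization used for the
published subtype runs. The Gleason field is treated as a plain integer with
a configurable cutoff; we do not guess which grading scale an upstream
cohort used.

## Landscape and subgroups

Per-gene directional frequencies are plain ratios over the chosen tumor
subset. The coverage curve captures, at each cutoff, the genes whose larger
directional frequency reaches the cutoff and reports the fraction of tumors
carrying at least one captured alteration; both outputs are non-increasing
in the cutoff by construction. Hotspots are maximal runs of ≥ `min_genes`
consecutive genes (per direction and chromosome) at or above the frequency
cutoff. "Above 10 %" is implemented inclusively so that the printed
threshold is usable as a boundary (a strict flag exists), frequencies are
per-direction (the combined-direction reading is not used), and a
`max_gap` option (default 0) can bridge isolated sub-threshold genes the way
visually contiguous bands do; bridged genes are never members, so every
member clears the cutoff. The hotspot's peak gene (maximal frequency,
ties to the lowest order index) is the default representative for
downstream clustering; a curated list can replace it.

Consensus clustering repeatedly subsamples 80 % of samples 1000 times per k
(both configurable), clusters each draw with k-medoids on Jaccard distance
over the binary profiles (average-linkage hierarchical clustering is the
alternative; the upstream tooling does not pin a distance or linkage, and
Jaccard is the natural metric for sparse binary alteration profiles), and
accumulates co-assignment proportions. Pairs of all-zero profiles get
distance 0. The cluster number is *suggested* by the elbow of the CDF-area
curve — the largest k whose relative area increase is ≥ 0.1 — but is never
silently applied: a user-fixed k always wins, matching the common practice
of choosing k by inspecting the consensus matrices and CDF curves. Mutual exclusivity tests every unordered
gene pair two-sided with BH correction across pairs; T2+ stage is parsed as
any `t_stage` beginning with T2, T3 or T4.

## The synthetic generator

`synthetic_config()` describes the reference simulation: 3000 genes across
20 chromosomes; two primary cohorts of 200 tumors and one all-metastatic
cohort of 150 (metastases carry expression but no PFS/Gleason, mirroring
the role of a metastatic-only profiling study); background Loss and Gain
rates of 5 % per gene; a subtype gene lost in 50 % of primaries and 60 % of
metastases with a small opposite-direction (Gain) rate so excluded samples
exist; two contiguous 8-gene regions at 15 % Loss emulating recurrent
alteration hotspots; and one planted co-alteration with +0.25 frequency
uplift in ST primaries, +0.50 in ST metastases, a −0.8 z expression shift
in carriers, hazard ratio 3 for adverse-expression ST primaries, and +0.25
probability uplift of Gleason ≥ 8 in the adverse stratum. PFS is
exponential (baseline median 60 months) with independent uniform censoring
on [0, 150] months — the simplest model satisfying the proportional-hazards
structure the clinical filter tests — and expression shifts attach to the
samples carrying the planted alteration, linking the genomic and
transcriptomic layers exactly the way the concordance filter assumes.
Sparse deleterious mutations (rate 0.001, 85 % damaging) exercise the
mutation-to-Loss path; the generator never emits a mutation on a gained
cell, so the conflict policy is exercised only deliberately in tests.

The generator does **not** emulate realistic allele spectra, segment-level
CNA correlation, cohort batch effects, or treatment structure. Passing
tests on synthetic cohorts therefore demonstrates the correctness of the
computations and the recoverability of planted signals under the assumed
model — not performance on real tumors.

## Numerical choices and limitations

* Two-sided Fisher p-values use the same relative tolerance for tied point
  masses as `stats::fisher.test`, and the implementation is cross-checked in
  the test suite against both `fisher.test` and a factorial enumeration
  oracle on every table with total count ≤ 12.
* The pipeline is RNG-free; only the generator and consensus clustering
  consume randomness, always behind a mandatory seed with the caller's RNG
  state restored afterwards. Identical inputs give bit-identical outputs,
  which the suite verifies down to written files.
* Test and validation problem sizes are chosen to make planted effects
  decisively recoverable while keeping the default suite fast: the full
  reference scale (3000 × 550) for recovery and null calibration, hundreds
  of random fixtures for the oracle comparisons, and 1000-sample survival
  simulations for hazard-ratio recovery within ±15 %.
* **The WT-null survival filter caps single-run sensitivity.** In WT tumors
  a genuine subtype-specific co-alteration has, by definition, no survival
  effect, so its WT logrank p is approximately uniform on (0, 1), and the
  requirement p ≥ 0.3 admits a true hit with probability ≈ 0.7 per dataset
  regardless of effect size or sample size. Across many seeds of the
  reference simulation the planted co-alteration is recovered at rank 1 in
  roughly two-thirds of runs, with essentially every miss caused by this
  filter; users who value sensitivity over strict subtype specificity can
  lower `survival_p_wt`. False-hit calibration is unaffected: under the
  null generator the median number of hits is 0.
* Cox ties use Breslow's approximation; with the near-continuous survival
  times generated here the choice is immaterial, but it is recorded rather
  than presented as the upstream authors' intent.
* Hotspot representative genes in real analyses are a curated choice; the
  peak gene is only a reproducible default.
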