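# prostamine

Prostate cancer is molecularly heterogeneous: common early lesions such as
*NKX3-1* or *RB1* loss define subtypes, but on their own they rarely explain
which tumors progress to metastasis or biochemical relapse. `prostamine`
mines harmonized multi-cohort tumor data for **subtype-specific
co-alterations** — second-gene Losses or Gains that are enriched within a
chosen subtype, further enriched in its metastases, expressed concordantly
with their copy-number direction, and associated with high Gleason grade and
shorter progression-free survival (PFS). It is aimed at cancer genomics
analysts working with GISTIC-style discretized copy-number calls,
deleterious-mutation flags, per-study expression z-scores and clinical
endpoints.

## The method

Directional alteration calls are derived per gene and sample: **Gain** when
the GISTIC call is > 0, **Loss** when the call is < 0 or the sample carries a
deleterious single-base substitution in the gene. For a subtype defined by a
gene *g* and a direction, samples split into ST (carrying the alteration) and
WT (diploid for *g*), each divided into primary and metastatic compartments.
Candidates then pass a three-stage cascade:

1. **Genomic** — keep gene×direction pairs with
   `f(ST primary) − f(WT primary) ≥ Δp` and
   `f(ST metastatic) − f(ST primary) ≥ Δm`, each supported by a one-sided
   Fisher enrichment test at Benjamini–Hochberg FDR ≤ `coalt_fdr`.
2. **Transcriptomic** — within ST tumors, altered samples must shift
   expression concordantly (Losses down, Gains up) in *both* compartments,
   with pooled-variance t-tests at BH FDR ≤ `dge_fdr`.
3. **Clinical** — median-stratifying ST and WT primaries by the candidate's
   expression, the adverse stratum (lower for Losses, upper for Gains) must
   be enriched for Gleason ≥ 8, show worse PFS in ST tumors (logrank
   p ≤ `survival_p_st`) and **no** PFS difference in WT tumors
   (p ≥ `survival_p_wt`) — the subtype-specificity requirement.

Surviving hits are ranked by primary enrichment, metastatic enrichment and
ST survival p, each transformed to a normalized rank

    NR = 1 − RankOrder / N_hits

and combined into the final score

    Score = 0.3·NR_primary + 0.3·NR_metastatic + 0.4·NR_survival.

Supporting analyses cover the alteration landscape (per-gene directional
frequencies, the tumor-coverage-versus-cutoff curve, contiguous alteration
hotspots of ≥ 5 genes above a 10 % frequency), consensus clustering of
binary alteration profiles with CDF-area based selection of the cluster
number, pairwise mutual-exclusivity testing, and subgroup–clinical
association reports.

Because the published cohort data are external, the package ships a
first-class synthetic generator (`simulate_dataset()` / `generate_dataset()`)
that emulates the full schema with planted co-alteration, expression,
survival and Gleason effects, so every stage is testable end to end.

## Worked example

```r
library(prostamine)

cfg <- synthetic_config(seed = 1)   # 3000 genes, 400 primaries + 150 mets,
                                    # one planted Loss co-alteration (G1500)
sim <- simulate_dataset(cfg)
sim$dataset
#> Harmonized prostate-cancer dataset
#>   genes:    3000
#>   samples:  550  (400 primary, 150 metastatic)
#>   cohorts:  primA, primB, metC
#>   expression layer: 3000 x 550

res <- run_prostamine(sim$dataset, "G0001", "loss", prostamine_profile())
res
#> Mining run: subtype G0001 (loss)
#>   groups: 218 ST-primary / 179 WT-primary / 86 ST-met / 62 WT-met
#>   final hits: 1
#>    gene direction primary_diff_observed met_diff_observed st_logrank_p score
#> 1 G1500      loss             0.2040131         0.2801365 2.129676e-19     0
```

The planted co-alteration G1500 is recovered as the only hit: lost ~20 %
more often in subtype primaries than in wild-type primaries, a further
~28 % more often in subtype metastases, and its low-expression stratum
relapses much earlier (logrank p ≈ 2e-19) in ST but not WT tumors. With a
single hit the normalized ranks — and hence the score — are 0 by
construction (`1 − 1/1`). The generator's two planted recurrent-loss
regions surface in the landscape scan:

```r
detect_hotspots(alteration_frequencies(sim$dataset$alterations),
                sim$dataset$annotation)
#>   chrom start    end direction n_genes peak_gene peak_frequency
#> 1  chr3     1 710000      loss       8     G0303      0.1781818
#> 2  chr9     1 710000      loss       8     G1202      0.1727273
```

A shell entry point with `landscape`, `mine` and `simulate` subcommands is
installed at `inst/cli/prostamine.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/prostamine.R", package="prostamine"))') \
    simulate --out data --seed 11
```

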