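# loadscreen

Genetic load scoring and drug-sensitivity association screens for cancer
cell-line cohorts.

## The problem

Beyond its few driver alterations, a cancer genome accumulates thousands
of *passenger* alterations. If passengers are mildly deleterious, their
cumulative burden — the **genetic load** — should reduce tumour fitness
and make cancer cells more sensitive to drug stress. Testing this on a
cell-line panel requires scoring load per cell line, normalising away
large between-tissue baselines, and screening load against drug response
at several resolutions under multiple-testing control. `loadscreen`
implements that analysis end to end for anyone working with
CCLE-style panels: segmented copy-number profiles (SEG), variant tables
(MAF-like), activity-area drug response, and optionally expression.

## The statistics at its core

Per cell line, two load scores:

* **Copy-number load** — the mean alteration *volume* of its segments,
  `volume = |log2 ratio| x (end - start + 1)`, altered segments only by
  default (amplifications and deletions contribute equally);
* **Mutation load** — the number of point variants with allelic fraction
  ≥ 10% outside a 125-gene driver exclusion list (a passenger count).

Loads and activity areas (area over the 8-point growth-inhibition curve)
are z-scored within tissue. Three screens then test H₁: ρ > 0 (Spearman,
with Pearson r reported alongside; exact permutation p-values for n ≤ 7):

| screen | unit | pooling | FDR family |
|---|---|---|---|
| pan-cancer | drug | all tissues | all drugs |
| pan-drug | tissue | all (cell, drug) pairs | all tissues |
| pair | tissue x drug | none | all tested pairs |

each per load type, Benjamini–Hochberg adjusted. A lasso regression
(`cv.glmnet`, one-SE rule) combines the two z-scored loads into a single
predictor per unit; units whose coefficients both shrink to zero are
excluded from the combined family. An expression layer correlates
standardized mean-rank single-sample gene-set scores (and a growth-factor
gene panel) with the loads, two-sided.

A fully seeded synthetic-cohort generator plants known (tissue, drug)
effects in z-space and inverts them through Hill dose-response curves, so
every stage of the pipeline is testable against ground truth without any
data download.

## Worked example

Plant one tissue–drug effect at Spearman ρ = 0.7 and recover it:

```r
library(loadscreen)
em <- data.frame(tissue = "TISSUE02", drug = "DRUG03",
                 beta = betaForRankCor(0.7), load_type = "cn")
gen <- generateCohort(cohortConfig(nTissues = 6, cellsPerTissue = c(12, 20),
                                   nDrugs = 8, effectMap = em), seed = 42)
loads <- computeLoads(gen$cohort)
pairScreen(loads, drugResponse(gen$cohort),
           tissues = "TISSUE02", drugs = c("DRUG03", "DRUG04"),
           loadType = "cn")
#>   scope            unit   tissue   drug load_type   rho   p_rho  q_rho     r
#> 1  pair TISSUE02|DRUG03 TISSUE02 DRUG03        cn 0.600 0.00903 0.0181 0.767
#> 2  pair TISSUE02|DRUG04 TISSUE02 DRUG04        cn 0.179 0.26214 0.2621 0.152
#>        p_r      q_r  n
#> 1 0.000421 0.000842 15
#> 2 0.294738 0.294738 15
```

The planted pair shows ρ = 0.60 over its 15 cell lines (the planted 0.7
minus sampling noise) at FDR q = 0.018; the null drug in the same tissue
is flat. The same cohort's pan-cancer screen dilutes the single-tissue
effect across all 88 lines (DRUG03: ρ = 0.24, q = 0.10) — exactly why the
screens are run at three resolutions. The two load measures themselves
are uncorrelated:

```r
loadIndependenceCheck(loads)
#>   values            r       p_r         rho     p_rho  n
#> 1    raw -0.048089097 0.6563753  0.02679492 0.8042821 88
#> 2      z -0.001414725 0.9895627 -0.02387316 0.8252642 88
```

For a full run (all screens, combined load, manifest, truth evaluation):

```r
runPipeline(list(simulate = list(nTissues = 6, cellsPerTissue = c(12, 20),
                                 nDrugs = 8), seed = 42), "my_run")
```

See `vignettes/genetic-load-screens.Rmd` for the models, parameter
choices and validation design.

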