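---
title: "Genetic load and drug sensitivity: models, screens and the synthetic cohort"
author: "loadscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic load and drug sensitivity: models, screens and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadscreen)
```

## The scientific question

Cancer genomes carry, besides the handful of driver alterations that fuel
tumour growth, thousands of *passenger* alterations with no driving role.
If passengers are individually mildly deleterious, their cumulative burden
— the **genetic load** — should reduce tumour fitness and make cancer cells
more vulnerable to therapeutic stress. `loadscreen` implements the analysis
needed to test that hypothesis on cell-line panels: score each cell line's
load from its copy-number and point-variant profiles, and ask whether load
predicts sensitivity to anticancer drugs, at three resolutions, under
false-discovery-rate control.

## The two load scores

**Copy-number load.** Each segmented interval contributes an *alteration
volume* `|log2 ratio| x length`, where length is `end - start + 1` (SEG
coordinates are treated as 1-based inclusive; any consistent convention
only rescales volumes uniformly, so the choice is fixed and documented
rather than configurable). A cell line's load is the *mean* volume of its
altered segments. Amplifications and deletions contribute equally through
the absolute value. Two denominator conventions exist: averaging over
altered segments only (default, `meanOver = "altered"`) or over all
segments. We default to altered-only because it is invariant to how finely
copy-neutral stretches happen to be segmented — a property of the
segmentation algorithm, not of the genome. The neutral threshold (default
`|log2| > 0`) is exposed for noisy segmentations.

**Mutation load.** The count of point variants after removing (i) variants
with allelic fraction below 10% — subclonal calls and artefacts; the
boundary value 0.10 is *kept*, since the filter removes fractions strictly
below the cutoff — and (ii) variants in a driver-gene exclusion list, so
that the count approximates passenger burden rather than driver activity.
The packaged list (`defaultDriverGenes()`, 125 symbols) is a curated
consensus of well-known oncogenes and tumour suppressors and is
user-replaceable; a classification filter (silent-only, missense-only, ...)
is available, with all classes counted by default.

**Normalisation.** Tissues differ hugely in baseline load and baseline
drug response, so loads and activity areas are z-scored *within tissue*
(subtract the tissue mean, divide by the tissue sample standard deviation,
`n - 1` denominator — conventional for the small tissues involved and fixed
so results reproduce bit-for-bit). Tissues with fewer than 8 cell lines are
excluded outright: a z-score against 7 or fewer peers is too unstable to
interpret, and their members are flagged rather than silently dropped.

## The three screens

Drug sensitivity is the **activity area**, the area over the relative
growth-inhibition versus concentration curve (computed here as the sum of
the eight inhibition fractions, range 0-8; higher = more sensitive). All
tests are one-sided for a *positive* Spearman correlation (sensitivity
increasing with load), with the Pearson coefficient reported alongside;
Spearman is primary because the load-response relation need not be linear
and the tissues are small enough for outliers to matter.

1. **Pan-cancer** — per drug, all tissues pooled (z-scores remove tissue
   baselines). FDR family: all drugs, per load type.
2. **Pan-drug** — per tissue, pooling (cell line, drug) pairs over all
   drugs; `n` is the pair count. Pooling drugs with different mean
   activities would confound the correlation, so activity is z-scored
   within each (tissue, drug) cell by default (`norm = "tissue-drug"`);
   plain within-tissue normalisation is available for comparison. FDR
   family: all tissues, per load type.
3. **Tissue-drug pairs** — every candidate combination with at least 7
   cell lines (the smallest unit size worth a rank test at all). Candidates
   default to the drugs and tissues flagged by the first two screens. FDR
   family: all tested combinations, per load type.

P-values are Benjamini-Hochberg adjusted within each screen x load-type
family, mirroring one results table per family. Untestable units (constant
values, too few observations) are excluded from the family, not assigned
placeholder p-values.

**Small-sample exactness.** For `n <= 7` the one-sided Spearman p-value is
an exact enumeration over all `n!` orderings (ties handled with average
ranks); the t-approximation with `n - 2` degrees of freedom is used only
above that. This matters for the pair screen, whose smallest units sit
exactly in the range where the approximation is weakest.

## The combined load

Copy-number and mutation loads are, empirically and by construction in the
generator, uncorrelated — they carry independent information — so a
combined predictor can outperform either. The combination is a lasso
regression of z-scored activity on the two z-scored loads
(`glmnet::cv.glmnet` along its default regularisation path), fitted per
analysis unit. The penalty is selected by cross-validated MSE with the
**one-standard-error rule**. We verified by simulation that this
configuration shrinks both coefficients to zero on uninformative units in
essentially 100% of replicates while recovering the correct weight
ordering on two-signal units; a deep custom penalty grid (descending four
orders of magnitude) with minimum-CV selection, by contrast, frequently
lands at near-OLS penalties on flat CV curves and reports spurious
non-zero weights on pure noise. `rule = "min"` remains available.

A unit is *usable* only when at least one load coefficient is non-zero;
unusable units carry no predictions and are excluded from the
combined-load FDR family. Fold assignment is a deterministic function of
`(seed, n)`; below 10 observations the fit falls back to leave-one-out.

By default the combined predictor is evaluated *in-sample* (predictions
from the same data that chose the weights), which can slightly inflate
significance but permits tiny units and direct comparison with the
single-load screens; `evaluation = "holdout"` substitutes the
cross-validation out-of-fold predictions.

## The expression layer

To connect load to transcriptional programs, each sample gets a per-set
enrichment score: rank all `G` measured genes ascending within the sample,
and standardize the mean rank of the `m` set members,

$$ s = \frac{\bar R_S - (G+1)/2}{\sqrt{(G+1)(G-m)/(12m)}} , $$

the Wilcoxon-style standardized mean-rank statistic — zero-mean and
approximately unit variance for random sets, antisymmetric under profile
reversal, and invariant under any monotone transform of the expression
values. This is a deliberate, closed-form surrogate for kernel-based
single-sample enrichment methods (GSVA and relatives): deterministic and
exactly testable. Consequence: pathway hit lists produced here will not
numerically match analyses run with GSVA itself, though strongly
load-coupled programs are recovered by either. Set and gene screens are
**two-sided** — both load-induced and load-suppressed programs are of
interest — unlike the drug screens, whose hypothesis is directional.

One caveat of rank-based per-sample scores is compositional: a strong
expression shift in one large set necessarily displaces the ranks of all
other genes. At realistic gene counts (thousands) the displacement is
negligible; with very small expression matrices it can induce weak
spurious anti-correlations in unrelated sets. The generator defaults for
expression tests therefore use 2000 genes.

The growth-factor panel screen applies the same two-sided test to
individual genes of a receptor-tyrosine-kinase-centred panel
(`defaultGrowthFactorPanel()`, curated from the EGFR/ERBB, FGFR, PDGFR,
IGF, VEGFR, TRK and EPH families plus ligands and related genes); any
panel file may be substituted.

## The synthetic cohort generator

`generateCohort()` draws cohorts whose structure mirrors a large
pharmacogenomic cell-line screen, with every planted parameter returned as
machine-readable truth:

* **Tissue structure**: 20 tissues of uneven size, 8-60 cell lines
  (drawn uniformly), matching screening panels that cap common cancers at
  ~60 lines and aim for a minimum near 8-15; an optional 7-cell tissue
  exercises the exclusion path.
* **Copy-number model**: per-tissue log-normal baselines for segment
  `|log2|` magnitude and length, per-cell segment counts of 15-60 plus 25%
  exactly-neutral segments (so the denominator convention is exercised).
* **Mutation model**: per-tissue negative-binomial variant counts (mean
  ~60, dispersion 4), 15% of variants below the allelic-fraction cutoff
  and 10% in driver genes, so both filters do real work. The two load
  channels are drawn independently — the generator's version of the
  empirical load-independence observation.
* **Dose-response**: 24 drugs, eight-point log-spaced concentration grids,
  Hill curves (slope 1.5, maximal inhibition 0.97). Effects are planted in
  z-space — `activity_z = beta * load_z + noise`, residual SD 0.8 — and
  inverted to an EC50 whose curve attains the target activity area
  exactly. Because the inversion is monotone, the planted *rank*
  correlation survives curve synthesis undistorted; `betaForRankCor()`
  converts a target Spearman correlation to the slope via the
  bivariate-normal relation. 5% of (cell line, drug) entries are set
  missing (not every line is screened for every drug) and are handled
  pairwise-complete everywhere downstream, never imputed.
* **Expression**: optional genes x cells Gaussian matrix with named gene
  sets; planted couplings add `gamma * load_z` to member genes. The
  default planted coupling strength in the calibration studies is
  `gamma = 0.8`, a strong, unambiguous transcriptional program.

What the generator does **not** emulate: genomic linkage and recurrent
breakpoints, segmentation artefacts, driver-phenotype correlations,
mutation signatures, expression covariance structure beyond the planted
shifts, and pharmacokinetics. Passing tests therefore demonstrate that the
*statistical machinery* recovers planted structure at honest error rates —
not that real cohorts satisfy the model.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the generator and the
  pipeline restore the caller's RNG state. Reruns of `runPipeline()` with
  the same config and seed are byte-identical (no timestamps in outputs).
* Writers render doubles with 17 significant digits, so every generated
  file round-trips bit-for-bit through the readers.
* Ties in Spearman use average ranks; exact enumeration applies the same
  tie-aware statistic.
* Degenerate inputs fail loudly and early: constant vectors are flagged
  untestable and excluded from FDR families with a warning; zero-variance
  tissues yield missing z-scores with a warning; cell lines without
  copy-number segments get a *missing* load, never zero; config errors
  (empty scope list, infeasible effect sizes, out-of-range FDR levels)
  abort before any computation.

## Problem sizes used in the validation studies

The packaged calibration and power studies use deliberately compact
cohorts so the full suite runs on a single CPU in a few minutes: null
calibration uses 200 replicate cohorts of 5 tissues x 12 cell lines x 6
drugs; the planted-pair power study uses 100 replicates of 6 tissues x 15
cell lines x 15 drugs (90 pairs, 3 planted at Spearman 0.7); the
independence check pools 480 cell lines across 20 tissues; the expression
study uses 100 replicates of 48 samples x 2000 genes x 12 sets. These
sizes are the package's validation conditions, chosen to mirror the
magnitudes of the motivating study (tissue sizes, drug counts, the n = 15
scale of tissue-drug units) at replicate counts that give stable rates.

One honest negative result is worth recording: with 3 true effects of
Spearman 0.7 hidden among 90 BH-corrected tests at n = 15, the per-pair
probability of clearing the 10% FDR bar is only ~0.5 — the effective BH
threshold near rank 3 of 90 demands an observed rho of ~0.67, which a true
rho of 0.7 exceeds only about half the time at that sample size. Screens
at this scale are *calibrated* but under-powered; single planted effects
in small candidate families, or effects at larger n, are recovered
reliably.

## Worked example

```{r example, eval = FALSE}
em <- data.frame(tissue = "TISSUE02", drug = "DRUG03",
                 beta = betaForRankCor(0.7), load_type = "cn")
gen <- generateCohort(cohortConfig(nTissues = 6, cellsPerTissue = c(12, 20),
                                   nDrugs = 8, effectMap = em), seed = 42)
loads <- computeLoads(gen$cohort)
pairScreen(loads, drugResponse(gen$cohort),
           tissues = "TISSUE02", drugs = "DRUG03", loadType = "cn")
```

Or end to end, with reports, manifest and truth evaluation:

```{r pipeline, eval = FALSE}
cfg <- list(simulate = list(nTissues = 6, cellsPerTissue = c(12, 20),
                            nDrugs = 8, effectMap = list(
                              list(tissue = "TISSUE02", drug = "DRUG03",
                                   beta = 1.2, load_type = "cn"))),
            seed = 42)
runPipeline(cfg, "load_screen_run")
```

## Known limitations

* The in-sample combined-load evaluation (the default, kept for
  comparability across unit sizes) slightly inflates combined-screen
  significance; use `evaluation = "holdout"` when unit sizes permit.
* The enrichment score is a rank statistic, not a distribution-calibrated
  enrichment method; its hit lists are comparable within this package, not
  across methods.
* The driver list and growth-factor panel are curated conveniences, not
  authoritative registries; both are plain text and meant to be replaced
  to match the user's annotation vintage.
* Pan-drug pooling treats (cell line, drug) pairs as exchangeable
  observations within a tissue; the reported `n` is a pair count and
  overstates the number of independent biological samples, which is one
  reason the pan-drug `n` runs into the thousands.
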