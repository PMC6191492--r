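---
title: "Methods: one-color microarray analysis of paired glial contrasts"
author: "glialarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-color microarray analysis of paired glial contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glialarray)
```

## The problem

Autoreactive T-helper-1 (Th1) cells that infiltrate the central nervous
system secrete effector molecules (prominently IFN-γ) that reprogram the
resident glia. A standard way to characterise that reprogramming is a
one-color microarray experiment: microglia and astrocytes are treated
either with plain medium or with Th1-conditioned supernatant, RNA is
hybridised to Agilent-style arrays, and per-cell-type differential
expression is compared across the two cell types to separate shared from
cell-type-specific transcriptional programs.

`glialarray` implements that full analysis as reusable, tested code:

1. feature-level QC and collapsing of on-chip replicate spots,
2. between-array normalization (quantile + global linear scaling +
   surrogate floor + log2),
3. empirical-Bayes moderated t-tests with Benjamini–Hochberg correction
   and 2-fold DEG calling per cell type,
4. the cross-cell-type "four-way" classification,
5. volcano and heat-map table preparation,
6. ΔΔCt quantification for qPCR validation, and
7. a synthetic-data generator with known DE truth so that the whole
   pipeline can be validated without any array data.

## Feature collapsing

Each probe is printed several times per array (four by default). The
collapsed value is the **geometric mean** of the surviving replicate
features' `gProcessedSignal` (gPS). A feature is excluded when it

(i) carries a manual flag,
(ii) was marked an outlier by the feature-extraction software,
(iii) lies outside an interquartile-range interval of the replicate
     population, or
(iv) has a pixel-intensity coefficient of variation above 0.5
     (strictly; a CV of exactly 0.5 survives).

Design choices the method description leaves open, and how this package
resolves them:

* **Order of rules.** The flag-based rules (i), (ii), (iv) run before the
  distributional rule (iii), so a corrupted spot cannot inflate the IQR
  that is supposed to catch it.
* **The IQR interval.** The default (`iqr_strategy = "median-centered"`)
  keeps features within `median ± 1.42 × IQR / 2` — a total interval
  width of 1.42 × IQR, matching the phrase "the interval of 1.42 ×
  interquartile range". A Tukey-style alternative
  (`"quartile-fenced"`, `[Q1 − m·IQR, Q3 + m·IQR]`) is available because
  the anchoring of the interval is genuinely ambiguous; neither reading
  is asserted to be the original software's. Whether the rule was applied
  to raw or between-array-normalized gPS is equally unresolved; it is
  applied to the raw replicate population here.
* **Small replicate counts.** With fewer than three surviving features a
  sample IQR cannot identify outliers (for two points, any symmetric pair
  lies outside the 1.42-wide interval by construction), so rule (iii) is
  only applied when at least three features survive.
* **Quartile method.** Linear-interpolation (type-7) quantiles
  throughout; the original software's convention is unknown.
* **All-excluded probes** become missing on that array, are kept as
  masked matrix entries, and are later imputed at the surrogate floor —
  the pipeline's own stand-in for "no reliable signal".

## Normalization

`normalize_pipeline()` runs, in this order:

1. **Quantile normalization**: every array's distribution of non-missing
   collapsed intensities is mapped onto the cross-array mean of order
   statistics. Ties receive the mean of the order-statistic means over
   their rank span. Missing entries are excluded from rank computation;
   arrays with unequal numbers of observed values are matched through
   linear interpolation on the common quantile grid.
2. **Global linear scaling**: each array is multiplied by
   `reference_value / p75(array)` so that its 75th percentile equals the
   series-wide reference of 1500 normalized gPS units exactly.
3. **Surrogate floor**: every value strictly below 15 finally normalized
   gPS units — and every masked entry — is substituted by exactly 15.
   Flooring follows scaling because the floor is defined on the finally
   normalized linear scale.
4. **log2 transform**; the matrix minimum is therefore
   `log2(15) ≈ 3.907`.

The scaling postcondition (per-array 75th percentile = 1500, relative
tolerance 1e-9) refers to the scaled matrix before flooring; flooring
can only touch values far below the 75th percentile, but imputing
previously-missing entries changes the column's count of observed
values, so the post-floor percentile can drift by a fraction of a unit
on arrays that had masked probes.

## Differential expression

Within each cell type the Th1 arm is contrasted against the medium arm
(n = 4 vs 4). Per gene:

* `log2FC = mean(treated) − mean(control)` on the log2 scale, plus
  replicate-paired per-replicate fold-change columns for the heat maps;
* a pooled two-sample variance `s²_g` on `d_g = n1 + n2 − 2` df;
* an empirical-Bayes **moderated t**: the hierarchical model
  `s²_g | σ²_g ~ σ²_g χ²_{d_g}/d_g`, `1/σ²_g ~ χ²_{d0}/(d0 s0²)` is
  fitted by the closed-form moment method on `log s²_g` — the excess of
  the empirical variance of
  `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)` over `ψ'(d_g/2)` equals
  `ψ'(d0/2)`, inverted with a Newton iteration; the mean of `e_g`
  identifies `s0²`. The posterior variance
  `s̃²_g = (d0 s0² + d_g s²_g)/(d0 + d_g)` gives
  `t_g = log2FC_g / (s̃_g √(1/n1 + 1/n2))` on `d0 + d_g` df.
* Degenerate regimes are handled explicitly: a non-positive excess
  estimates `d0 = ∞` (fully pooled variances; total df capped at the
  summed residual df), a single usable gene estimates `d0 = 0` (the
  ordinary pooled t), and an all-zero-variance, zero-effect gene gets
  `p = 1` and a flag.
* Raw p-values are BH-adjusted per cell type (two separate families,
  matching the separate per-cell-type DEG counts), and a gene is a DEG
  when `p_adj < 0.01` and `|FC| ≥ 2`. The fold-change boundary is
  inclusive by default ("FC ≥ 2.0"); `deg_criteria(strict_fc = TRUE)`
  gives the strict "more than 2-fold" reading.

The moderated t here is the standard empirical-Bayes estimator of the
limma family, authored in this package; the test suite cross-checks it
against both a step-by-step brute-force recomputation (trigamma
inversion by bisection instead of Newton) and, where limma is installed,
against `limma::eBayes`. Equivalence with proprietary array-analysis
software cannot be asserted.

## Four-way comparison

The union of the two cell types' DEG sets is classified on a 3×3 grid:

* Fold changes of genes with corrected `p > 0.05` in a cell type are
  first **adjusted to FC = 1** (log2 = 0). This cutoff is deliberately
  distinct from the DEG-calling alpha of 0.01: both constants are kept
  as stated, not harmonized.
* A gene is `up`/`down` in a cell type when its adjusted log2FC is
  `≥ 1`/`≤ −1` (2-fold; the threshold is a parameter), else `unchanged`.
* The 9-cell table is the canonical partition (its counts always sum to
  the union size); the aggregate classes are derived views. Genes
  discordant between cell types (up in one, down in the other) appear in
  both relevant cell-type-specific aggregates and are also reported
  separately.

A generic **regulator activation z-score** is provided for user-supplied
signed regulator→target networks:
`z = (n_consistent − n_inconsistent)/√(n_consistent + n_inconsistent)`,
with `|z| > 2` (strictly) required for an `activated`/`inhibited` call.
It is a documented generic replacement for proprietary
upstream-regulator analyses; no knowledge-base content ships with the
package.

## Visualization tables

* **Volcano**: every transcript of the universe is classified `green`
  (`p < 0.01` and `|log2FC| > 2`), `red` (p only), `orange` (FC only) or
  `grey`. The `|log2FC| > 2` coloring threshold (4-fold) is kept
  literal-to-its-source even though the DEG gate is 2-fold; a
  `fc_class_threshold = 1, fc_strict = FALSE` call reproduces the DEG
  gate instead. Corrected p feeds the y-axis (`p_column = "p_raw"` is
  available); `p = 0` maps to a display ceiling of 320.
* **Heat maps**: per gene and cell type the four replicate-paired
  log2FC columns are averaged; values above 6 are capped at 6. The cap
  is one-sided by default, exactly as stated; `mode = "symmetric"` also
  caps at −6. The gene panel is user-supplied.

## ΔΔCt quantification

`ΔCt = Ct_target − mean(Ct_Hprt1, Ct_Gapdh)` per sample (the arithmetic
mean of the two reference Cts equals geometric-mean normalization on the
expression scale — the description names the two reference genes but no
combination rule), arms are averaged, `ΔΔCt = ΔCt_Th1 − ΔCt_medium`,
`FC = 2^(−ΔΔCt)` with amplification efficiency fixed at 2. Regulation
calls use strict 2-fold lines (`FC = 2` exactly is not called). Whether
reported kinetics average ΔΔCt before or after exponentiation is not
stated; per-replicate fold changes are exponentiated first and
summarized as mean ± SD, and the fold change from the mean ΔΔCt is
emitted alongside.

## The synthetic-data generator

`sim_config()` encodes the emulated study design: 2 cell types × 2
treatments × 4 biological replicates (16 arrays), every probe printed 4
times. Its statistical choices, none of which are dictated by the
analysis method itself:

* **Gene classes** (`null`, `common_up/down`, `astro_up/down`,
  `micro_up/down`, `discordant`) with exact largest-remainder counts;
  defaults put 10% of genes in non-null classes with |log2FC| drawn
  uniformly from [1.5, 3].
* **Noise model**: additive Gaussian on the log2 scale (log-normal
  intensities), matching the downstream log2 analysis. Per-gene noise
  variances are scaled inverse-chi-square (`df = 8`, `scale = 0.09`,
  mean SD ≈ 0.3 log2 units), so the moderated-t shrinkage step has real
  variance heterogeneity to estimate.
* **Baselines** `N(8, 2²)` log2 units: wide enough that a realistic few
  genes fall under the surrogate floor after scaling, exercising the
  floor on gene probes as well as on controls.
* **Array distortion**: per-array multiplicative scale factors with
  log2-SD 0.2 — exactly what quantile normalization plus scaling must
  remove.
* **Spot noise** (`spot_sd = 0.15` log2 units) on each on-chip replicate
  feature; this parameter exists only in the generator, since the
  analysis never models spot-level error explicitly.
* **Contamination**: 1% manually-flagged features, 1% software-outlier
  features (these also get a 10× intensity spike so that exclusion rule
  (ii) is consequential and distinguishable from rule (iii)), 2% of
  features with pixel CV in (0.55, 1). Negative controls (100 per array)
  get low log-normal intensities (~3 linear units) that land below the
  floor after typical scaling.

What the generator does **not** emulate: scanner physics, background
subtraction, probe-sequence effects, correlated (batch) noise,
intensity-dependent variance, or multiple probes per gene. Passing
recovery tests therefore demonstrate correctness of the statistical
machinery under its own assumptions, not performance on real arrays.

All randomness derives from `sim_config(seed = )`; identical
configurations emit byte-identical files.

## Problem sizes and verification

The test suite validates every stage against independent oracles
(hand-written quantile/BH/moderated-t recomputations, round-trip checks
of emitted files) and runs the full pipeline end-to-end on the default
design of 5,000 genes × 16 arrays. Parameter recovery — sensitivity
≥ 0.90 and empirical FDR ≤ 0.05 at alpha 0.01 — is averaged over ten
seeded replicates of that design via the direct matrix route (the
collapsed-intensity model without file emission), which keeps the whole
check under a minute. `scripts/acceptance.R` re-runs the file-route
pipeline at the same design and writes the headline quantities as JSON.

## Known limitations

* Probe = gene is assumed throughout (no multi-probe summarization).
* The moderated t supports the two-group equal-variance design only —
  the design of this study — not covariates or multi-factor models.
* Quantile normalization assumes most genes are unchanged; designs with
  very asymmetric regulation would bias fold changes slightly.
* Real-array replay (e.g. from public series matrices) is possible by
  assembling an `intensity_matrix()` by hand, but no downloader is
  included and published DEG counts are not a validation target here.
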