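---
title: "Cross-species congruence of volumetric sex differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species congruence of volumetric sex differences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcongr)
```

## The scientific question

Humans show reproducible sex differences in regional brain volume; mice,
the main mammalian model for mechanistic work on sex-biased brain
development, show their own. Whether the two patterns agree — region by
region, in direction and magnitude — determines how far mouse findings
translate. `sexcongr` implements a quantitative comparison over a fixed
set of 60 homologous brain regions (28 bilateral pairs plus 4 midline
structures), and asks a second-order question as well: do regions whose
volumetric sex differences agree across species also have more similar
regional gene-expression profiles?

## The statistical model, stage by stage

### Standardized sex effects

For each region, the sex effect is the coefficient $\beta_1$ from ordinary
least squares on the z-scored volume:

$$z(\mathrm{vol}) = \beta_0 + \beta_1\,\mathrm{sex} +
\beta_2\,(\mathrm{age}-\overline{\mathrm{age}}) + \beta_3\,\mathrm{TTV} +
\beta_4\,\mathrm{QC} + \varepsilon$$

Because the response is standardized, $\beta_1$ is a unitless effect size.
Female is the reference level, so $\beta_1 > 0$ means male-biased. TTV
(total tissue volume) isolates regional effects from global scaling; the
QC covariate is the Euler number of the cortical reconstruction in
human-style tables and background strain (a treatment-coded factor) in
mouse-style tables — both flow through the same fitting code in
`fit_sex_effect()`. Inference is the usual two-sided t test on the
residual degrees of freedom; `fit_sex_effects()` adds Benjamini–Hochberg
control at $q \le 0.05$ (via `stats::p.adjust`). Whether TTV is z-scored
before entering as a covariate is exposed (`zscore_ttv`) but cannot change
$\beta_1$, its t or p value — only the TTV coefficient's own scale.

Variance differences between the sexes are tested with the classic Levene
statistic (one-way ANOVA on absolute deviations from the group **mean**)
on volumes residualized for TTV, age, and the QC covariate. The
mean-centered form is the default because the analysis this package
reproduces names the test without qualification; the median-centered
(Brown–Forsythe) variant is available through `center = "median"`.

### Batch harmonization

Multi-cohort mouse data are harmonized with `harmonize_batches()`, a
parametric empirical-Bayes location–scale adjustment: per region, data are
standardized against a fit that retains sex and age; per-batch means and
variances of the standardized data are shrunk toward across-region
empirical priors (normal for locations, inverse-gamma for scales,
method-of-moments hyperparameters, fixed-point iteration); the shrunken
shifts and scales are removed and the covariate structure restored. With
one batch the function is the identity. The implementation agrees with
the reference genomics implementation to ~1e-7 on simulated tables (see
`test-harmonize.R`). One consequence worth knowing: because the procedure
removes between-batch variance, z-scored effect sizes computed *after*
harmonization are slightly larger than those computed on batch-free data
of the same residual structure — about +3% under the default synthetic
batch settings. This is a property of harmonize-then-standardize
pipelines generally, not of this implementation.

### Robust cross-species correlation

Congruence between the 60 paired effect sizes is measured with the
percentage-bend correlation (`percentage_bend_correlation()`), not
Pearson, because a single extreme region (the BNST, with a mouse effect
near 1) could otherwise dominate. For each variable a robust scale
$\hat\omega$ is the $m$-th order statistic of absolute deviations from
the median, $m = \lfloor(1-\beta_{\mathrm{bend}})n + 0.5\rfloor$;
deviations about a bend-adjusted location are clamped to $[-1, 1]$ and a
product-moment statistic is formed from the clamped scores, with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. The bend constant defaults to
0.2 — the default of the reference robust-statistics implementation,
resisting 20% contamination per variable. Ties in the order statistic are
taken as-is (no interpolation); incomplete pairs are deleted pairwise and
counted; p-values are two-sided.

### Similarity scores and transcriptional congruence

Per region, the **anatomical sex-effect similarity score** is the product
$\beta_H \cdot \beta_M$: positive when the species agree in direction,
negative when they disagree, larger when both effects are large.
**Transcriptional similarity** is the Pearson correlation, across
homologous genes, of the two species' z-scored regional expression
profiles. The expression matrices are built by volume-weighted averaging
of samples into regions (uniform weights for mouse voxel data), reflecting
left-hemisphere rows into missing right-hemisphere slots, intersecting
with a one-to-one homologous-gene map, and z-scoring each gene across
regions. Z-scoring happens after intersection and reflection (the
matrix-final form); the per-region correlation is computed on the z-scored
values — "scaled expression" is taken to mean the z-scored matrices, and
since Pearson correlation is not invariant to per-gene rescaling applied
before a per-region correlation, this ordering is part of the method
definition here. Regions lacking expression data (the medial amygdalar
nucleus and medial preoptic area in the bundled map) are flagged
`expression_available = FALSE` in the region map rather than hard-coded,
and simply carry `NA` transcriptional scores.

The two per-region measures are then correlated across regions
(`similarity_vs_expression_correlation()`, percentage-bend again), overall
and within compartments.

### Gene-subset permutation nulls

For a biologically defined gene subset (X-linked, hormone-signaling, ...),
`gene_subset_null()` draws `n_resamples` (default 10,000) same-sized
subsets uniformly **without replacement** from the homologous-gene
universe, recomputes the transcriptional similarity and its correlation
with the anatomical scores for each, and reports the add-one permutation
p-value $p = (1 + \#\{r_{\mathrm{null}} \ge r_{\mathrm{obs}}\})/(B+1)$
(two-sided by doubling the smaller tail, capped at 1). The +1 convention
means p is never exactly 0 from a finite resample. Draws are not
stratified by expression level — a documented simplification of "random
subsets of the same size".

## The built-in effect-size table and its compartment split

`builtin_pair_table()` returns the 60 published paired effect sizes
exactly as printed (3 decimals), with per-species significance flags. The
cortical/non-cortical split is not itemized in the source material; this
package assigns the 13 bilateral cortical regions (agranular insula,
anterior cingulate, entorhinal, perirhinal, piriform, posterior parietal
association, primary auditory, primary motor, primary somatosensory,
primary visual, retrosplenial, temporal association, ventral orbital;
26 rows) to `cortical` and everything else — including hippocampal
subfields, subiculum, cerebellar cortex, and midline brainstem
structures — to `non_cortical`. The 26/34 split matches the sample sizes
implied by the published subgroup p-values. The assignment lives in the
bundled TSV and is fully configurable through `load_homologous_regions()`.

Two caveats about the printed table. First, the published overall
correlation (r = 0.30) is reproduced from the printed values to within
rounding (we obtain 0.2977). Second, the published *cortical* subgroup
value is unstable in its own source (0.33 in the text, 0.31 in the
corresponding figure caption), and from the 3-decimal printed betas the
bend-0.2 correlation over the 26 cortical rows is 0.218 — no anatomically
plausible membership we examined reproduces 0.33 from the printed
precision. The package reports what the printed data give; the
discrepancy is documented rather than absorbed by re-tuning membership or
the bend constant. The non-cortical value reproduces to 0.175 vs 0.16.

## The synthetic-data generators

`simulate_cohort()` emulates the *structure* of the two study cohorts,
not their raw data: the human-style default has 597 females / 496 males
aged 22–35, a TTV sex shift of 1.3 standardized units, male residual
variance inflation (ratio 1.2), Euler numbers, sibling pairs, and one
batch; the mouse-style default has 213 females / 216 males aged postnatal
days 56–90, no TTV shift, equal variances, two background strains, and 18
acquisition cohorts with additive offsets (SD 0.2 standardized) and
multiplicative noise scales (0.8–1.25). Default per-region true effects
are the built-in published effect sizes of the matching species, so a
default two-species simulation plants a cross-species congruence of
about 0.3.

A region's volume is TTV-proportional allometry plus a scaled structured
term: $V = b\,(\mathrm{TTV}/\overline{\mathrm{TTV}}) + s\,\eta$, with
$\eta$ collecting the sex effect, age and QC slopes, batch structure, and
per-sex scaled noise. The scale $s$ is solved per region from the
quadratic $\mathrm{Var}(V) = s^2$ implied by the spec's variance budget
(including the TTV–sex covariance path), which makes the planted
standardized effect equal the estimand of `fit_sex_effect()` up to
$O(1/n)$ — verified by the parameter-recovery tests (|bias| < 0.05 at
n = 400). Specs whose variance shares exceed the budget are rejected
rather than silently rescaled. Gaussian noise is the default; a scaled
$t_3$ option exercises the robustness advantage of the bend correlation
over Pearson.

`simulate_expression_pair()` gives each region a latent shared gene
profile: each species' row is
$\sqrt{|\rho_r|}\,\mathrm{latent} + \sqrt{1-|\rho_r|}\,\mathrm{own} +
\mathrm{noise}$, so the expected per-region cross-species correlation is
$\approx \rho_r$ (attenuated by
$\mathrm{shared}^2/(\mathrm{shared}^2+\mathrm{noise}^2)$, about 1% at the
defaults). Human symbols are upper-case, mouse symbols title-case, paired
one-to-one in the returned map.

What the generators deliberately do **not** model: spatial covariance
between regions (each region's noise is independent), realistic
volumetric allometry exponents, family-level correlation beyond the
family labels themselves, image- or voxel-level structure, and
expression-level stratification of genes. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to everything real data can do.

## Numerical choices and edge cases

- Constant input to `zscore_response()` is a hard error — silent zeros
  would propagate as fake null effects.
- `percentage_bend_correlation()` errors when a robust scale estimate is
  zero (more than $m$ ties at the median) rather than returning NaN.
- Rank-deficient designs raise a singular-design error
  (`lm(singular.ok = FALSE)`), never silent aliasing.
- Genes constant across regions are dropped (with a count) before
  z-scoring; regions with no expression keep `NA` scores and are dropped
  pairwise from score correlations.
- `r = ±1` gives $t = \pm\infty$ and p = 0 in the analytic correlation
  tests; permutation p-values by construction are in (0, 1].
- One-per-family subsetting and every simulation run under an isolated,
  restored RNG state, so library calls never perturb a caller's seed.

## Problem sizes used in the shipped tests

The validation suite favors exact small-instance oracles (enumerating all
20 subsets of a 6-gene pool, all 720 orderings of six p-values, hand
normal-equations solutions) plus moderate Monte-Carlo runs: 200
replicates of n = 400 cohorts for estimator bias, 500 replicates for
correlation recovery, 2000 replicates for Levene calibration, 500 null
pipeline runs at 500 resamples for permutation uniformity. These sizes
give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping the whole suite around five minutes.

## Known limitations

- The bundled effect-size table is printed at 3 decimals; statistics that
  are unstable at that precision (the cortical subgroup correlation) will
  not match values computed from unrounded effect sizes.
- The empirical-Bayes harmonization assumes roughly Gaussian residuals
  within batch; heavy-tailed batches will be over- or under-shrunk.
- The permutation null treats genes as exchangeable under uniform
  sampling; co-expression structure means the effective null may be
  narrower than biological reality.
- `pearson_correlation()` and the t-based p-values assume independent
  pairs; regions are anatomical neighbors and not strictly independent,
  which is precisely why the permutation machinery exists for the
  gene-subset questions.

## A worked example

```{r demo}
demo <- run_table1_demo()
demo
```

```{r synthetic, eval = FALSE}
# a fully synthetic two-species run with known ground truth
out <- run_pipeline(list(seed = 1, synthetic = TRUE, n_resamples = 1000),
                    outdir <- tempfile("sexcongr_run_"))
str(out[c("congruence_r_all", "ttv_beta_human", "similarity_r_all")])
```
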