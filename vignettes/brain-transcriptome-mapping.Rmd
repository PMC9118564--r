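---
title: "Disease-related brain transcriptome mapping: methods and design"
author: "BrainTxMap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-related brain transcriptome mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainTxMap)
```

## The problem

Imaging-transcriptomic studies correlate regional gene expression with
regional imaging phenotypes, but most do not involve the diagnosis at
all, so the genes they surface need not be related to the disease.
BrainTxMap implements a two-stage design that puts the diagnosis back
in the loop. The running application is Alzheimer's disease: regional
amyloid burden (AV45 PET SUVR) parcellated on a 360-region cortical
atlas (180 per hemisphere), a cohort staged CN / EMCI / LMCI / AD, and
brain-wide microarray expression maps for ~10,000 genes on the left
hemisphere (which the expression atlas samples far more densely than
the right).

## Stage 1: imaging-diagnosis maps

For a case-control contrast $c$ and region $j$, we fit by ordinary
least squares

$$ y_{sj} = \beta_0 + \beta_{dx} \, \mathrm{case}_s + \beta_1\,\mathrm{age}_s
   + \beta_2\,\mathrm{sex}_s + \beta_3\,\mathrm{edu}_s + \varepsilon_{sj}, $$

where $\mathrm{case}_s \in \{0,1\}$ pools the contrast's case stages
into a single binary indicator (the contrasts are phrased "control vs
case", so ordinal stage coding is deliberately not used). The per-ROI
significance is the two-sided p-value of $\beta_{dx}$, reported as
$-\log_{10}(p)$; the vector of these values over the analyzed ROIs is
the *imaging-diagnosis map* for that contrast.

Because disease severity progresses EMCI $<$ LMCI $<$ AD, contrasts
pool only stage-contiguous case sets. Over the full staging this gives
exactly six comparisons — CN vs EMCI, CN vs LMCI, CN vs AD, CN vs
EMCI+LMCI, CN vs LMCI+AD, CN vs EMCI+LMCI+AD — and never CN vs
EMCI+AD, which would skip the intermediate stage. `buildContrasts()`
enforces this structurally.

Design choices worth stating explicitly:

* **Two-sided p-values.** Significance maps are rendered unsigned, and
  direction-agnostic inference is the field default; a one-sided
  variant would bake in the expectation that amyloid only increases.
* **Stage-1 ROI significance defaults to raw $p < 0.05$**, with
  Bonferroni over the ROI family available via
  `significantRois(..., correction = "bonferroni")`. Published
  per-contrast ROI counts rarely state the correction behind them, so
  both modes are exposed and the one used is logged.
* **Education enters as continuous years**; no banding.
* **Covariate coding.** Sex is male = 1 / female = 0; any consistent
  binary coding yields identical diagnosis-coefficient inference, and
  the suite verifies invariance of $t$ and $p$ under affine changes of
  any covariate.

Numerically, the fits use a QR decomposition shared across all ROIs of
a contrast (the design is identical; only the response changes), which
is both fast and the numerically stable choice. Rank-deficient designs
are a hard error naming the collinear columns. p-values are floored at
$10^{-300}$ before $-\log_{10}$, so a perfect fit yields a large finite
value instead of an infinity while preserving ranking.

## Stage 2: spatial correlation and family-wise control

Each gene's expression vector over the analyzed ROIs is correlated
(Pearson) with each contrast's $-\log_{10}(p)$ map; the p-value comes
from the usual transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom, with $n$ the number of pairwise-complete ROIs for
that gene. Three choices matter here:

* **Correlation target.** The default target is the *unsigned*
  $-\log_{10}(p)$ map, the quantity the significance maps display.
  `correlateGenes(..., target = "signed")` offers
  $\mathrm{sign}(\beta)\cdot(-\log_{10} p)$ for direction-aware
  analyses.
* **Missing expression values** (sparsely sampled regions) are handled
  by pairwise deletion, with `n_used` recorded per test. Genes with
  fewer than three complete pairs, or zero variance over the common
  ROIs, are *excluded and counted*, never assigned $r = 0$: the
  correlation is undefined there, and silent zeros would distort the
  test family.
* **The Bonferroni family is the set of tests actually performed**,
  pooled over every (gene, contrast) pair:
  $p_{\mathrm{adj}} = \min(1, p \cdot m)$ with $m$ the pooled count.
  With six contrasts and 10,027 usable genes and no exclusions,
  $m = 60{,}162$. The family size is logged on every run because the
  correction is only valid for the family actually tested. A
  per-contrast family (`family = "per-contrast"`) is exposed as a
  documented variant.

Genes significant in *every* contrast form the intersection set, which
is then partitioned by membership in a user-supplied disease-annotation
list (the DisGeNET role) into confirmatory ("known") and novel genes.
Symbols are upper-cased on both sides first, because annotation
databases and expression atlases capitalize inconsistently.

## The synthetic study generator

Restricted-access cohort and atlas data cannot ship with a package, so
`syntheticConfig()` / `generateCohort()` / `generateExpression()`
generate data with the statistical structure the analysis assumes,
plus a ground-truth sidecar for scoring recovery. The defaults *are*
the study conditions:

| Parameter | Default | Rationale |
|---|---|---|
| group sizes | 255 / 296 / 218 / 202 (CN/EMCI/LMCI/AD) | the cohort's demographic table |
| age | truncated normal, per-group means 76.4/71.8/74.7/75.9, SD 6.5–8.4, range 55–95 | per-group demographic moments |
| sex | Bernoulli, per-group male fraction from the same table | — |
| education | truncated normal 16.13 ± 2.75, range 6–20, all groups | the pooled moments; one group's printed mean (12.12) is inconsistent with every other group and is treated as a typo, with per-group overrides exposed |
| ROIs | 180 left-hemisphere labels `L_R###_ROI` | left-hemisphere restriction |
| baseline SUVR | N(1.1, 0.05) per ROI | typical amyloid SUVR scale |
| effect sizes | 0.10 / 0.20 / 0.30 SUVR for EMCI / LMCI / AD | monotone severity; weakest stage sits at effect/noise = 0.5 |
| noise SD | 0.2 SUVR | realistic residual spread |
| affected ROI fraction | 0.4 | a substantial but not brain-wide signal |
| covariate slopes | age 0.005 SUVR/yr, sex 0.02, education −0.002 | nonzero so covariate adjustment is exercised, not vacuous |
| genes | 10,027; 12 signal genes at target spatial r = 0.6 | post-filter gene count; intersection-set scale; mid-range of the published per-gene correlations (≈0.35–0.65) |
| annotation list | 1,877 genes, 4 of them signal genes | measured-and-annotated gene count; known/novel split |
| expression missingness | 0.1 per (gene, ROI) | sparse regional sampling |

The trait model is
$y_{sj} = b_j + \delta(d_s)\,a_j\pi_j + \beta^\top \mathrm{cov}_s +
\varepsilon_{sj}$ with affected indicator $a_j$, per-ROI shape
$\pi_j \sim U(0.5, 1)$ and i.i.d. noise. Signal genes are built by the
standard mixture construction $\rho z + \sqrt{1-\rho^2}\,e_\perp$ on
standardized vectors, but with the noise component explicitly
orthogonalized against the profile first, so each signal gene's
realized sample correlation with the *true, noiseless* effect profile
equals the target exactly (well inside the intended ±0.05 band).
Correlating against the true profile rather than an estimated
significance map keeps the ground truth sample-independent: stage-2
recovery then tests the whole pipeline, estimation error included.
Covariates are drawn from truncated normals rather than resampled
empirically because only moments, not microdata, are available.

Cohort and expression generation use distinct seed streams (the
config seed, and the config seed + 1) so each is independently
reproducible; all output is a pure function of the config.

**What the generator does not emulate.** Noise is independent across
ROIs. Real brain maps are spatially autocorrelated, and the Pearson
p-values of stage 2 treat ROIs as independent samples, so on real data
the family-wise error control is likely anticonservative; a
spatial-autocorrelation-preserving null ("spin test") is deliberately
out of scope because the implemented method uses plain Pearson
p-values. Passing the calibration suite therefore demonstrates
correctness *under ROI exchangeability*, not robustness to spatial
structure. Site/batch effects, APOE genotype, scanner differences and
longitudinal structure are likewise not modeled, and no
mixed-effects or voxel-level analysis is offered.

## Verification strategy and problem sizes

The test suite checks every fitted statistic against independent
oracles: an explicit normal-equations solver (matrix inversion, not
QR) for the regressions at $10^{-10}$ relative tolerance, direct
sum-formula and numerical-integration computations for Pearson $r$ and
$p$ at $10^{-12}$, permutation nulls for both (1,000 label
permutations for the regression $t$; $10^5$ draws for the Pearson
$p$, compared at two Monte-Carlo standard errors plus a small fixed
allowance for the $t$ approximation to the exchangeability null at
$n = 10$), and `stats::lm` / `cor.test` / `p.adjust` as library
cross-checks.

Calibration and recovery are exercised at sizes chosen to make the
Monte-Carlo assertions sharp while keeping the default suite fast:
null-uniformity of stage-1 p-values pools 50 replicate cohorts at the
full 971-subject, 180-ROI scale (KS test at $\alpha = 0.01$);
family-wise error is measured over 100 replicate null studies at a
reduced scale (100 subjects, 500 genes), bounded by
$0.05 + 2\,\mathrm{SE}$; and recovery of the planted signal genes and
affected ROIs is scored over 20 studies at the full scale (10,027
genes, family size 60,162), requiring ≥ 0.95 sensitivity for both.
`scripts/acceptance.R` re-runs the full-scale pipeline end to end and
writes the headline counts it computes.

## Degenerate inputs and tie-breaking

* Phenotype rows with missing covariates are dropped at load (no
  imputation procedure is defined for this design); unknown diagnosis
  labels and duplicate subject ids are hard errors.
* All label sorting uses radix order (byte order), so output ordering
  is locale-independent and byte-reproducible across machines.
* Numeric round trips: every writer formats doubles with `%.17g`, the
  shortest representation guaranteed to reparse to the identical
  IEEE-754 value, so write → read → write is byte-identical and
  loading never silently perturbs values.
* ROI labels are opaque beyond their `L_`/`R_` hemisphere prefix; a
  label with neither prefix is a hard error listing the offenders.

## Known limitations

Beyond the spatial-autocorrelation caveat above: the intersection rule
is all-or-nothing across contrasts (a gene significant in five of six
contrasts is excluded, with no intermediate evidence tier); the
annotation partition is a membership test, not an enrichment analysis;
and the stage-1 ROI significance counts depend on the chosen
threshold mode, which is why both modes are exposed and logged rather
than one asserted as canonical.
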