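---
title: "Linking blood gene expression to serum compound modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking blood gene expression to serum compound modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`momint` analyzes small two-group multi-omic cohorts — the motivating
setting is minimal hepatic encephalopathy (MHE) in cirrhotic patients, with
blood transcriptomics, a targeted serum metabolite panel and a cytokine
panel measured on the same eleven patients. This vignette documents the
statistical model behind each stage, the defaults and why they were chosen,
what the synthetic cohort generator does and does not emulate, and the
numerical conventions.

## Step 1: quality control, variance stabilization, differential testing

**Metabolite QC.** A metabolite is retained only if (1) its fraction of
missing values (non-detected peaks) is *strictly below* 20% in every
experimental group, and (2) *at least* 50% of its measured values lie above
the limit of detection. The 20% rule is exclusive and the 50% rule
inclusive; both thresholds are arguments of `metabolite_qc_filter()`. The
filter is idempotent.

**Variance stabilization.** `vst_normalize()` is a simplified,
deterministic variance-stabilizing transform for non-negative intensity
data. Each sample is affinely calibrated (gain and offset) against the
across-sample median feature profile by weighted least squares with weights
proportional to 1/reference²; the weighting matters because intensity noise
is predominantly multiplicative, and unweighted least squares lets the
high-abundance tail impose offsets that corrupt low-abundance features.
The calibrated data then receive a common generalized log,
`glog2(x, b) = log2((x + sqrt(x² + b²))/2)`, with `b` selected on a
log-spaced grid (40 points from a quarter of the 0.1% quantile up to the
99% quantile) to minimize the absolute slope of the per-feature SD against
the rank of the per-feature mean. This is an approximation to full
maximum-likelihood variance stabilization; the test suite verifies its two
defining properties (exact removal of affine sample distortions; ≥ 80%
flattening of a multiplicative mean–variance trend). Constant input falls
back to an identity-like transform with a warning.

The *cytokine* block is the exception: a 14-feature panel cannot support
the SD-trend calibration fit, so in the pipeline cytokines enter the
clustering and PLS stages through a plain `log2` (the asymptote of the
glog for strictly positive data). Group comparison of cytokines never uses
the transform at all (rank tests below).

**Moderated t.** Genes and metabolites are tested per feature with a
two-sample contrast and empirical-Bayes variance shrinkage:
`s²_post = (d₀·s₀² + d_g·s_g²)/(d₀ + d_g)`, with the moderated statistic
`t = logFC / (s_post·√(1/n₁ + 1/n₂))` on `d₀ + d_g` degrees of freedom.
The prior `(d₀, s₀²)` is estimated by the method of moments on `log s_g²`
(trigamma inversion by Newton's method); `d₀` is capped at 10⁶ for
numerical stability and `s₀²` floored at 10⁻⁸, which also covers
zero-residual-variance features. `d₀ = 0` recovers the ordinary t-test
exactly; `d₀ → ∞` gives a z-like statistic with the pooled prior variance
(both are tested). Per-sample weights are accepted (uniform by default —
no weighting source is defined for these data) and missing values reduce
the per-feature sample sizes and degrees of freedom. Log-fold-changes are
case minus control throughout, with the second factor level as the case
group.

**Cytokines.** `wilcoxon_panel()` runs exact two-sided rank-sum tests
(full enumeration whenever the total sample size is ≤ 20 and there are no
ties; normal approximation with tie/continuity correction otherwise),
reports raw-scale medians and IQRs per group, and attaches a
Fligner–Killeen homoscedasticity diagnostic that is reported but never
gates the test (no principled action on failure exists for n this small).

**Multiplicity.** Benjamini–Hochberg step-up within each omic; `NA`
p-values propagate and are excluded from the number of tests. Significance
means q < 0.05 everywhere.

## Step 2: compound modules

The union of FDR-significant metabolites and cytokines is clustered on the
distance `d = √(2(1 − r²))`, with `r` the absolute Spearman correlation
(average-rank ties; constant features get r = 0 with a warning). PAM
(deterministic BUILD + SWAP on the precomputed distance) is compared with
k-means (on a classical MDS embedding of the distance, up to
min(n − 1, 10) dimensions — k-means needs coordinates, which the distance
does not supply directly) and average-linkage hierarchical clustering,
over k = 2..min(10, n − 1); the method/k pair with the largest mean
silhouette wins, ties broken by smaller k and then by method order (PAM
first). Mean silhouettes below 0.25 trigger a weak-structure warning.
Members of singleton clusters get silhouette width 0.

Module profiles are built on z-scored features: members negatively
correlated with the running average are flagged sign −1 and flipped before
re-averaging (two passes; a flat average — exact cancellation — falls back
to the first member as reference orientation).

Clustering operates on the variance-stabilized scale; because the
correlation is rank-based, this choice is nearly immaterial, which is why
it is the default rather than an option to agonize over.

## Step 3: per-module PLS

`fit_pls()` is NIPALS PLS2 in regression mode: components maximize the
X–Y covariance, X is deflated per component, and the score iteration is
initialized with the Y column of maximal variance (deterministic),
converging on the X-score vector at tolerance 10⁻¹⁰ within 500 iterations.
Both blocks are autoscaled by default — the responses mix pg/ml and µM —
with centering-only available. Zero-variance predictors are dropped with a
warning. Training R² is cumulative on the scaled response block.

`q_squared_loo()` implements strict leave-one-out cross-validation: every
fold refits from scratch, *including* re-estimation of the centering and
scaling vectors on the training fold, and `Q² = 1 − PRESS/TSS` accumulates
in training-fold-standardized response units with TSS around the
training-fold means. Q² is cumulative over components (a per-component
alternative would hide whether added components help prediction overall).
Defaults: A = 2 components, interpretation on component 1.

**Component geometry.** In these cohorts every compound module separates
the two groups strongly, so all module response blocks share one dominant
case-control axis. The first PLS component of every module model captures
that shared axis, and the *module-specific* covariation — in the synthetic
cohorts, the latent factor shared by the module's compounds and its coupled
genes — appears on component 2. `gene_loadings()` and `fit_all_modules()`
therefore expose the component choice (`ranking_component`, default 1);
analyses that need module identity rather than overall disease association
should rank on component 2. This geometry is a property of any design in
which per-feature significance at n = 11 forces the group axis to dominate
feature variance; it is verified directly in the test suite.

## Step 4: enrichment and networks

`fisher_ora()` is the one-sided hypergeometric over-representation test
("an unusually large overlap"), with a two-sided Fisher option. Two
significance tiers are flagged — primary (p < 0.05) and relaxed (p < 0.1)
— because borderline pathways are often carried along for interpretation;
the relaxed tier is always explicit, never silently merged.

`ranked_enrichment()` regresses set membership on a standardized ranking
index: gene ranks are mapped to centered normal quantiles (top of the
ranking at large positive values), making the test invariant to the
loading scale and exactly antisymmetric under ranking reversal. Wald z and
two-sided p per set; BH across sets, per module by default (a global
option across modules would couple unrelated models). Quasi-separation
triggers a ridge-penalized IRLS refit (penalty 1 on the slope), flagged in
the output. Sets with fewer than 3 members in the universe are skipped.

`pathway_network()` connects significant terms (both tiers, attribute-
flagged) when the Jaccard index of their member sets within the test
universe reaches 0.1 (configurable); curated pathway-relation databases
are deliberately out of scope, and gene-overlap crosstalk is the
documented stand-in. `multi_enrichment_network()` builds the bipartite
term–module graph from the per-module ranked enrichments; terms linked to
two or more modules are flagged `central`, module-specific terms
`peripheral`. Both builders sort nodes and edges canonically, so output is
invariant to input order; graphs are written as edge-list TSV and GraphML.

## The synthetic cohort generator

The generator reproduces the statistical structure the analysis assumes,
with ground truth for parameter recovery:

* **Design.** 6 cases / 5 controls. Desk-scale 5000 genes (full-scale
  60000 for the 8×60K array format); 143-metabolite catalog with class
  counts 8/21/17/1/15/81 and side-chain annotation parsed from the
  "C x:y" notation; 14-cytokine panel.
* **Planted effects.** 847 gene effects with |log2FC| ~ U(0.7, 2); the 29
  metabolite effects with their reference log2 fold changes (e.g.
  PC aa C36:4 at −0.7436); 6 cytokine effects derived as
  log2(case median / control median) from the reference serum
  concentration medians.
* **Gene model.** log2-normal baselines with means U(6, 14); per-gene
  variances from a scaled-inverse-χ²(d₀ = 4, s₀² = 0.05) prior — exactly
  the hierarchical model the moderated t assumes, so prior recovery is a
  fair test.
* **Latent modules.** Six modules: the six cytokines; three
  glycerophospholipid modules split by side-chain carbons/double bonds
  (≤ 40C with ≤ 5 double bonds; ≤ 40C with > 5; > 40C with ≥ 5); a
  sphingomyelin/small-compound module for the remaining increased
  metabolites; and the decreased amines (Val, alpha-AAA, spermine). Lipid
  assignment follows the carbon/double-bond rules and is approximate for
  compounds the rules do not cover. Each module has one latent factor
  `f_m = shift_m·(group indicator − mean) + u_m` with |shift| = 3.5
  within-group SD units; a member with planted log2FC gets loading
  `λ = logFC / shift`, so planted group differences are delivered exactly.
  Member values are `baseline + λ·(f_m + e)` with member distortion
  e ~ N(0, 0.22²) — residual noise proportional to the loading, giving a
  uniform within-module correlation (≈ 0.98, matching the near-block-
  diagonal correlation structure such panels show) — plus a 0.01-log2
  analytic noise floor.
* **Identifiability stylization.** The within-group factors `u_m` are
  orthogonalized in-sample against the group contrast and against each
  other. At n = 11 the chance correlation between independent factor
  realizations is large (sd ≈ 0.35) and can merge planted modules or leak
  coupled-gene signal across modules; orthogonal draws make the planted
  ground truth identifiable. Real cohorts carry no such guarantee — this
  is the main respect in which passing recovery tests overstate what the
  method can do on real data.
* **Gene–module coupling.** 40 planted genes per module share the module's
  factor with coefficient `logFC / shift`; their planted signs are aligned
  with the module's direction (co-regulation), which makes each coupled
  set direction-coherent in the loading ranking.
* **Class correlation (optional).** Non-module features can share latent
  chemical-class factors (`class_cor`); the default is 0 (independent
  nulls), which keeps the null-calibration properties transparent.
* **LOD censoring.** `censor_below_lod()` deterministically replaces
  values below a per-feature threshold with `NA`, emulating non-detected
  peaks for QC testing. The default cohort is fully observed, matching a
  panel delivered "without missing values".

Everything is driven by one seed; identical configurations produce
byte-identical files. What the generator does **not** emulate: array image
artifacts, probe-level effects, batch/run-order drift, heteroscedastic
cytokine group variances, compositionality, and any correlation between
the null features and the disease process. Effects of those on real data
are outside what the test suite can certify.

A known consequence of the design: with 35 strong true serum effects among
157 tests, BH at 5% admits on the order of one false serum feature per
cohort. These intruders are uncorrelated with everything, so the
silhouette criterion isolates them as singleton clusters, and the selected
k on a given cohort is typically 6 plus the number of intruders; the modal
selected k across a seed suite is 6. This is the FDR doing exactly what it
promises, not a failure of the clustering.

## Numerical conventions and degenerate inputs

* BH: step-up; `NA` excluded from the test count; output order = input
  order.
* Trigamma inversion: Newton, 50 iterations, relative tolerance 10⁻¹⁰.
* NIPALS: tolerance 10⁻¹⁰ on the relative score change, ≤ 500 iterations;
  degenerate (zero) weight vectors abort with an error; A is capped at
  min(n − 1, predictors).
* Constant features: correlation 0 with warning (clustering); dropped
  with warning under autoscaling (PLS); all-tied panels give p = 1 with
  warning (Wilcoxon).
* Ranking ties are broken by feature id, and all network output is
  canonically sorted, for bit-reproducibility.
* Empty significant lists: ORA returns p = 1 with a warning; the pipeline
  ends gracefully after step 1 ("no_modules") when fewer than 3 serum
  features are significant.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the study's own scale (11
samples; 5000 genes; 143 + 14 serum features), a 10-seed recovery suite
for clustering, 100-replicate permutation nulls for Q², 400–500-replicate
nulls for the ranked enrichment calibration, and 2000-feature null cohorts
for the Kolmogorov–Smirnov uniformity checks — sizes chosen so the whole
suite runs in about a minute on a laptop while keeping Monte-Carlo error
well below the tested margins.

## Known limitations

* The variance-stabilizing fit is a deterministic approximation, not the
  full maximum-likelihood calibration; arrays with strong nonlinear
  distortions are not handled.
* Leave-one-out Q² on 11 samples has high variance; the per-module values
  should be read as a tier (good / none), not estimated to two decimals.
* The ranked enrichment is a linear-in-rank logistic model: a gene set
  split coherently between both extremes of a ranking is invisible to it.
* Module membership is hard (one module per feature); overlapping or fuzzy
  modules are out of scope.
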