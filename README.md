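# momint

Multi-omic module integration for small case-control cohorts.

`momint` implements a four-step analysis that links blood gene expression to
serum metabolite and cytokine *modules*, of the kind used to study minimal
hepatic encephalopathy (MHE) in cirrhotic patients — a setting with very few
samples (a dozen patients), thousands of transcripts, a targeted
143-metabolite panel and a 14-cytokine panel:

1. **Per-omic differential testing.** Metabolites pass a two-rule QC filter
   (missingness < 20% in every group; ≥ 50% of measured values above the
   limit of detection), genes and metabolites are variance-stabilized with a
   generalized log transform and tested with an empirical-Bayes moderated t
   (`s²_post = (d₀s₀² + d_g s_g²)/(d₀ + d_g)`, prior estimated by the method
   of moments on `log s_g²`); cytokines are tested with the exact Wilcoxon
   rank-sum test on raw concentrations. All tests use Benjamini–Hochberg
   FDR < 0.05.
2. **Module discovery.** The union of FDR-significant serum features is
   clustered with PAM on the distance `d = √(2(1 − r²))`, where `r` is the
   absolute Spearman correlation; the number of clusters (and the method,
   against k-means and average-linkage hierarchical clustering) is chosen by
   the mean silhouette width. Each module gets a signed, scaled consensus
   profile.
3. **Integration.** One PLS2 regression (NIPALS) per module: significant
   genes are the predictor block, the module's compounds the joint response
   block. Models are scored by cumulative R² and by leave-one-out Q²
   (`Q² = 1 − PRESS/TSS`, refitting — including re-centering and re-scaling
   — on every fold).
4. **Enrichment and networks.** Fisher (hypergeometric) over-representation
   of the differential gene list; logistic-regression enrichment of gene
   sets along the PLS loading ranking; a pathway–pathway crosstalk graph
   (Jaccard gene overlap) and a bipartite term–module graph with
   central/peripheral term roles.

Because cohorts like this are rarely public, the package ships a fully
specified **synthetic cohort generator**: 11 samples (6 MHE / 5 controls), a
143-metabolite catalog with the class composition of a targeted serum kit
(8 acylcarnitines / 21 amino acids / 17 biogenic amines / 1 hexose /
15 sphingomyelins / 81 glycerophospholipids), a 14-cytokine panel,
847 planted gene effects, 29 planted metabolite and 6 planted cytokine
effects, six latent correlation modules with gene–module coupling, and a
ground-truth record for parameter-recovery testing. See the methods
vignette (`vignettes/multiomic-integration.Rmd`) for the model and every
default.

## Worked example

```r
library(momint)
cfg <- pipeline_config(synthetic = default_cohort_config(seed = 101), seed = 101)
report <- run_pipeline(cfg, outdir = "momint_demo")
print(report)
```

```
momint run report (v0.1.0, seed 101): complete
  step1: significant genes 854, metabolites 32, cytokines 6
  step2: pam clustering, k = 9 (mean silhouette 0.614)
  step3: per-module PLS
   module n_compounds A    R2_cum    Q2_cum
 module_1          14 2 0.9839683 0.8065594
 module_2           6 2 0.9769809 0.7723573
 module_3           3 2 0.9899427 0.8155340
 module_4           3 2 0.9951821 0.8248519
 module_5           3 2 0.9897841 0.7562249
 module_6           1 2 0.9946493 0.6656644
 module_7           1 2 0.9903685 0.5370197
 module_8           1 2 0.9700718 0.2029424
 module_9           6 2 0.9920425 0.7355050
  step4: 36 sets; ORA primary 7, relaxed 0
```

Reading the report: step 1 recovers essentially the planted signal — 854
significant genes against 847 planted effects, the 6 responsive cytokines,
and 32 significant metabolites (29 planted plus 3 false discoveries, about
what BH-FDR at 5% admits). In step 2 the six multi-member clusters are the
six planted modules (the 14 short low-unsaturation phosphatidylcholines,
the 6 cytokines, the three 3-member lipid/amine modules and the 6-compound
sphingomyelin axis); the three singletons are the false-discovery
metabolites, which correlate with nothing and are isolated by the
silhouette criterion. In step 3 every multi-member module model fits with
R² ≳ 0.97 and predicts with leave-one-out Q² ≈ 0.74–0.82, while the
singleton (noise) models show how Q² degrades without real structure. All
per-step tables, module profiles, loadings, enrichment results and both
networks (edge-list TSV + GraphML) are written under `outdir`.

A thin command line sits in `inst/scripts/momint-cli.R`
(`simulate`, `run-all` subcommands); per-stage access is via the exported
functions (`metabolite_qc_filter()`, `vst_normalize()`,
`moderated_ttest()`, `wilcoxon_panel()`, `select_modules()`, `fit_pls()`,
`q_squared_loo()`, `fisher_ora()`, `ranked_enrichment()`, ...).

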