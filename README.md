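# shinegem

Trauma patients with shock-induced endotheliopathy (SHINE) — catecholamine-
driven damage of the vascular endothelium — show distinct plasma metabolic
profiles on admission, and those profiles predict mortality. Because the
endothelium of a critically ill patient cannot be biopsied, its
intracellular metabolic state has to be *inferred*: quantified plasma
metabolites are integrated as boundary constraints into a genome-scale
metabolic model (GEM) of the endothelial cell, and the contextualized model
is interrogated with flux balance analysis.

`shinegem` implements that analysis as a tested R pipeline, for
computational biologists and trauma researchers who want to run, audit, or
extend it:

1. **Preprocessing** — missingness filtering (> 30% rule), iterative
   random-forest imputation, log2 + Pareto scaling, perfect-correlate
   removal, Hotelling-T² PCA outlier detection.
2. **Phenotyping** — complete-linkage hierarchical clustering of patient
   profiles (k = 4 by default), biology-anchored A–D letter assignment,
   PLS-DA variable-importance (VIP) ranking of discriminant metabolites.
3. **Contextualization** — per phenotype, exchange bounds set to
   `(FC·Q1, FC·Q3)`, where `(Q1, Q3)` are quartiles of the baseline
   network's sampled exchange-flux distributions and
   `FC = mean(phenotype)/mean(healthy)` is the plasma fold change; the
   model is then relaxed to feasibility by an L1-minimal slack LP over the
   constrained bounds only.
4. **Validation** — leave-one-out cross-validation over constrained
   exchanges: hold one out, re-sample the flux polytope, compare the
   predicted flux population against the constrained model (Welch t-test,
   Benjamini–Hochberg FDR) and summarise accuracy as R² of predicted means
   vs held-out constraint midpoints.
5. **Task activities** — maximal-flux scoring of metabolic tasks
   (sources → products, closed medium) on each phenotype model,
   row-normalized to [-1.5, 1.5] and clustered.
6. **Clinical report** — median [IQR] / n (%) summaries, phenotype-D-vs-
   rest Kruskal–Wallis and chi-square tests, endotheliopathy-of-trauma
   classification (syndecan-1 ≥ 40 ng/mL), Kaplan–Meier survival.

The constraint-based core — a metabolic network container, FBA over
`max c'v  s.t.  S·v = 0, lb ≤ v ≤ ub` (with its own two-phase simplex), and
seeded hit-and-run flux sampling in null-space coordinates — lives in the
package, so no external solver is needed.

Patient-level data of this kind are not publicly deposited, so the package
ships a **synthetic cohort generator** (99 patients in three injury-
severity strata + 20 healthy controls, 62-metabolite panel, four planted
phenotypes with succinate elevated in phenotype D, planted missingness,
outliers, and phenotype-conditional clinical covariates and survival) and a
**toy endothelial-like network** (36 metabolites, 44 reactions) with a
12-task catalog. All shipped results are computed on these synthetic
fixtures; the pipeline itself is agnostic and accepts any network in its
JSON dialect or SBML L3/fbc, any concentration CSV, and any task catalog of
the documented schema.

## Worked example

Contextualize the toy network for two designed plasma profiles — one
glycolysis-dominant (glucose and lactate ~2-fold up), one
catabolism-dominant (fatty acids, amino acids, succinate up) — then score
tasks and cross-validate:

```r
library(shinegem)

net      <- build_toy_ecgem()
baseline <- sample_fluxes(net, 1000, seed = 7)
mapping  <- toy_exchange_mapping()
fcs      <- two_phenotype_fold_changes()

glyc <- contextualize_from_fc(net, baseline, fcs$A_like, mapping)
cata <- contextualize_from_fc(net, baseline, fcs$D_like, mapping)

tam <- task_activity_matrix(list(glycolytic = glyc, catabolic = cata),
                            build_toy_task_catalog())
round(tam$raw[c("atp_glycolysis", "lactate_from_glucose",
                "malcoa_synthesis", "tca_nadh"), ], 2)
#>                      glycolytic catabolic
#> atp_glycolysis            15.50      6.20
#> lactate_from_glucose      13.95      5.58
#> malcoa_synthesis           9.69     24.24
#> tca_nadh                   9.69     24.24

loo_crossvalidate(glyc, n_samples = 400, seed = 8)
#> <ValidationReport> 12 held-out exchanges (0 failed); R^2 = 0.9839
```

The glucose-elevated profile has ~2.5-fold higher glycolytic ATP and
lactate-from-glucose capacity; the fatty-acid/amino-acid-elevated profile
has ~2.5-fold higher TCA-NADH and malonyl-CoA synthesis capacity (more
acetyl-CoA headroom). Held-out exchange constraints are recovered from the
remaining ones with R² ≈ 0.98.

The full analysis — synthetic cohort through clinical report — is a
numbered workflow under `analysis/`:

```sh
Rscript analysis/01_simulate.R      # cohort + toy network + task catalog
Rscript analysis/02_preprocess.R    # 62 -> 54 metabolites, impute, scale, outliers
Rscript analysis/03_phenotyping.R   # clusters, letters, VIP, heatmap
Rscript analysis/04_contextualize.R # 4 phenotype models
Rscript analysis/05_validate.R      # leave-one-out exchange validation
Rscript analysis/06_tasks.R         # task activities, archetypes, ratios
Rscript analysis/07_clinical.R      # summary table, tests, Kaplan-Meier
```

Each stage prints what it found and writes its tables under `results/`.

## Repository layout

```
R/                  package code (network core, sampler, pipeline stages)
analysis/           numbered workflow scripts (the analyses themselves)
scripts/            acceptance script
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (modelling choices and rationale)
inst/extdata/       reference outcome-count table (plain text)
```
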