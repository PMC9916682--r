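---
title: "Methods: plasma phenotyping and endothelial GEM contextualization"
author: "shinegem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma phenotyping and endothelial GEM contextualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`shinegem` implements a pipeline from quantified plasma metabolomics of a
trauma cohort to phenotype-specific endothelial-cell metabolic models and
their inferred intracellular task activities. The stages are: metabolomics
preprocessing; phenotype discovery; contextualization of a constraint-based
metabolic network per phenotype; leave-one-out cross-validation of the
contextualized boundary constraints; metabolic-task activity scoring; and
clinical statistics. Because patient-level data of this kind are not
shipped, the package includes a synthetic cohort generator and a toy
endothelial-like network that exercise every stage end to end; this
vignette records the modelling choices, their defaults, and what the
synthetic results do and do not demonstrate.

# Preprocessing

The raw input is a samples x metabolites table of quantified concentrations
with explicit missingness. The pipeline order is fixed: missingness filter,
imputation, log2 + Pareto scaling, perfect-correlate removal, PCA outlier
removal — one pass, no refit loop.

* **Missingness filter.** Metabolites missing in strictly more than 30% of
  samples are removed; a metabolite missing in exactly 30.0% is retained.
* **Imputation.** Iterative random-forest regression in the missForest
  style, built on `ranger`: missing cells start at column medians, columns
  are cycled in order of increasing missingness, each regressed on all
  others, and the cycle repeats until the relative change of the imputed
  cells drops below 1e-4 or 10 iterations. Observed cells are never
  modified, and the procedure is seeded.
* **Normalization.** `log2` per cell, then per column
  `x' = (x - mean) / sqrt(sd)` (Pareto scaling). Pareto scaling leaves each
  column with variance equal to its pre-scaling standard deviation: it
  damps high-variance metabolites without flattening them to unit variance
  the way autoscaling would. Constant columns map to zero with a warning.
* **Perfect correlates.** For any metabolite pair with `|r| >= 0.999` the
  later column is dropped. The threshold is a declared convention for
  "tracks 1:1"; the synthetic cohort plants one such pair
  (fumarate generated identically from malate) to exercise it.
* **Outliers.** Hotelling-T2 on the (PC1, PC2) and (PC1, PC3) score
  planes, with the classical F-based 95% ellipse
  `2 (n-1)(n+1) / (n (n-2)) * F(2, n-2)`. A sample beyond the limit in
  either plane is removed. Components with numerically zero variance are
  excluded, with the limit adjusted to the available component count.
  Outlier detection runs on the log2 + Pareto matrix; running it on
  autoscaled data is a plausible alternative we did not adopt, because the
  same matrix feeds clustering and keeping a single normalized view avoids
  a second, inconsistent geometry.

# Phenotype discovery

Patients are clustered with Euclidean distance and complete linkage and
the tree is cut at `k = 4`; `k` is a parameter, not a constant, because the
four-group structure is an assumption of the analysis, not of the code.
Complete linkage is deterministic given the input order; equal-height
merges resolve to the lowest-index pair.

Cluster numbers are mapped to letters by a declared rule: the cluster with
the highest mean of the succinate marker is `D`; the remaining clusters are
lettered `A`, `B`, `C` in dendrogram leaf order. The letters encode biology
(D = high succinate, high mortality), not cluster size, and only `D` is
anchored — the mapping of the remaining letters to any external labelling
is conventional.

Discriminant metabolites are ranked by PLS-DA VIP: a partial least squares
fit against the one-hot class matrix (2 components by default, matching the
two-component score plots such analyses report), with the standard
weighted-sum-of-squares VIP whose squared scores average to 1. The fit and
VIP come from `mixOmics`.

# Contextualization

The network object is a standard constraint-based model: stoichiometric
matrix S, flux bounds in mmol·gDW⁻¹·h⁻¹, uptake negative / secretion
positive at exchange reactions. Contextualization constrains only boundary
exchanges mapped to measured plasma metabolites ("transport" and
"exchange" are used interchangeably for this boundary set; the constrained
set is always the mapped exchanges):

1. Sample the baseline network's steady-state polytope and take per
   reaction the first and third quartiles (Q1, Q3) of its sampled flux
   (type-7 linear-interpolation quantiles — the single quantile convention
   used package-wide, also for clinical medians/IQRs).
2. Compute per metabolite the fold change FC = mean(phenotype
   concentration) / mean(healthy concentration) on **raw** imputed
   concentrations. A fold change of log/Pareto values is not a ratio of
   means, so normalization is deliberately bypassed here.
3. Apply candidate bounds (FC·Q1, FC·Q3) and take (min, max) of the pair
   so ordering survives any sign pattern. Both quartiles are multiplied —
   the literal reading of scaling the quartile window — rather than
   rescaling the window around a centre. Mapped exchanges without a
   measured fold change keep their baseline quartile bounds; measured
   metabolites without a mapped exchange are reported as unmapped, never
   silently dropped.
4. If the constrained model is infeasible, solve an L1-minimal slack LP
   that may widen only the constrained bounds (internal reaction bounds
   are never touched — the base network's biology stays intact), widen
   exactly the reactions with positive slack, and log each widening.

With all fold changes equal to 1 the constrained toy model is feasible
with an empty relaxation log (self-consistency), because the baseline
sample mean is a feasible point whose exchange coordinates lie inside the
quartile windows.

# Flux analysis substrate

**LP solver.** All linear programs (FBA, feasibility certificates, slack
relaxation, interior-point search) go through a self-contained two-phase
dense tableau simplex (Dantzig pivoting, Bland fallback after 200
iterations, degenerate-artificial drive-out, redundant equality rows
removed by QR). The problems here are tiny (≤ ~150 variables) and often
degenerate; the implementation is cross-checked in the test suite against
a brute-force vertex-enumeration oracle on every fixture. Feasibility
tolerance is 1e-6 throughout. Infinite bounds are clamped to ±1000 at
load (the conventional cap); an optimum pinned to such an artificial cap
on the objective is reported as unbounded rather than optimal.

**Degenerate optima.** FBA returns one optimal vertex; downstream code
uses only objective values or sampled distributions, never a unique-flux
assumption.

**Sampling.** Flux sampling is hit-and-run in null-space coordinates: an
orthonormal basis N of the null space of S guarantees S·v = 0 exactly for
every iterate; the walk starts at a Chebyshev-style interior point
(maximum relative bound margin, found by LP), discards `100 * n_reactions`
warm-up steps and keeps every 10th step. Warm-up and thinning are
configurable; the defaults are declared, not derived, since no specific
sampler is mandated by the analyses this package supports. Reactions are
canonically sorted by id before the basis is built, so sample sets are
invariant to reaction order up to column relabeling, and a fixed seed
reproduces the matrix bit for bit.

# Cross-validation

For each constrained exchange `r` in a contextualized model: reset `r` to
its baseline bounds, re-sample, and take the sampled population of `r` as
the model's prediction of the held-out constraint. Two quantities are
reported per reaction: a Welch two-sample t-test (no variance-equality
guarantee between sampled populations) of the prediction against the fully
constrained model's population for the same reaction, with
Benjamini–Hochberg adjustment across reactions; and the global R² of
predicted means against held-out constraint midpoints. Reporting both is
deliberate: a small q-value marks *difference*, so whether "significant"
means agreement or disagreement depends on the direction convention, and
the R² is the less ambiguous accuracy summary. The per-reaction flux is
the only quantity entering the t-test — it is the reading that yields one
p-value per held-out exchange. A leave-one-out model that turns infeasible
is recorded as a failed prediction, not an error.

On the toy two-profile design (below) the pooled R² across both models'
held-out exchanges is ≥ 0.95. Exchanges that are stoichiometrically forced
by the remaining constraints are recovered exactly (R² = 1 within 1e-6).

# Task activities

A task is sources (allowed uptakes), products (demand reactions added on
the fly), an objective reaction to maximize, and a cofactor whitelist. The
evaluation environment is the closed-medium convention: uptake is closed
for every exchange except the task's sources (which keep the model's
contextualized bounds) and the whitelisted cofactors (oxygen and CO2 by
default, at base-network bounds — a task whose whitelist omits `o2_e` is
anaerobic). Secretion stays open for all exchanges, because closing it
would block steady-state operation of lumped linear pathways. Internal
demand reactions (a single consumed metabolite, e.g. the maintenance ATP
window) are freed from both floor and ceiling: the task probes capacity,
not maintenance. A feasible task with no productive flux scores 0 and is
flagged blocked.

Raw task x model activities are row-normalized by a linear min–max map
onto [-1.5, 1.5]. The plausible alternative — z-scores clipped at ±1.5 —
is rejected because a stated scale "between -1.5 and 1.5" implies attained
bounds; the switch is a config option. Constant rows map to zeros with a
flag. Task rows are clustered with Euclidean distance and complete
linkage, like the patient profiles.

# Synthetic cohort generator

The generator emulates the study design the pipeline assumes: 99 patients
in three injury-severity strata (20/40/39), 20 healthy controls, a
62-metabolite panel, four latent phenotypes with planted sizes 33/17/24/21
(A/B/C/D) among the 95 non-outlier patients, 8 metabolites with >30%
missingness, under 2% elsewhere, one perfectly correlated metabolite pair,
4 multivariate outliers, and phenotype-conditional clinical covariates and
survival.

* **Concentrations.** Independent log-normal per metabolite with shared
  σ_log = 0.4 and per-phenotype mean shifts in log2 space. The named panel
  metabolites carry the biology: succinate +2.5 log2 in D (its defining
  marker, and the top discriminant by construction), glucose/lactate up in
  A, glutamine up in B/C, fatty-acid and amino-acid analogs up in D; each
  phenotype additionally has three generic markers at +1.6 log2
  (≈ 3-fold, a realistic effect for strongly perturbed plasma
  metabolites). These defaults were calibrated once so that the planted
  structure is strong but not trivial: complete linkage recovers it with
  adjusted Rand index ≥ 0.9 and succinate ranks in the top-3 VIP across
  seeds. Units are arbitrary; only fold structure is meaningful.
* **Missingness.** Planted high-missingness metabolites draw a rate in
  (0.35, 0.55) with a deterministic count strictly above 30%; background
  columns are capped below 2%. The mask is reproducible from the seed.
* **Outliers.** Four patients are displaced ±6 score-standard-deviations
  along the cohort's first two latent components (the dominant variance
  directions spanned by the phenotype shifts). Displacement along the
  leading components is what makes a profile land far outside the PCA 1–2
  (or 1–3) confidence ellipse where the detector looks — an aberration
  orthogonal to all leading structure would hide in later components.
* **Clinical covariates.** Drawn per phenotype from log-normal (skewed
  biomarkers; e.g. syndecan-1 location 190 ng/mL in D) or normal (vitals)
  distributions with locations at the phenotype medians of the cohort
  being emulated. The endotheliopathy flag is derived from the simulated
  syndecan-1 with the ≥ 40 ng/mL rule, never drawn independently.
* **Survival.** A constant per-phenotype daily death hazard
  `h = 1 - (1 - p30)^(1/30)` calibrated to 30-day mortalities
  30.3%/29.4%/16.7%/76.2% (A/B/C/D), right-censored at day 30. A constant
  hazard reproduces S(30) but deliberately not the early-death
  concentration a real shock cohort shows within 24–72 h; no time-varying
  hazard is modelled.

What the generator does **not** emulate: instrument artefacts (drift,
batch effects, censored-at-LOD missingness — the mask is random, not
intensity-dependent), correlated metabolite blocks beyond the planted
pair, and covariate–metabolite coupling within phenotype. Passing
recovery tests on this cohort shows the pipeline's machinery is correct
and calibrated, not that real plasma data are this clean.

# Toy network and task catalog

The toy endothelial-like network (36 metabolites, 44 reactions) exposes
the routes the task catalog probes: lumped glycolysis (2 ATP and 1.8
pyruvate per glucose, with 0.1 of the glucose carbon leaking to
methylglyoxal as a fixed-fraction triose-phosphate spillover), lactate
fermentation, pentose-phosphate and thioredoxin/NADPH branches, pyruvate
oxidation, a lumped TCA cycle (4 NADH per acetyl-CoA), respiration
(2.5 ATP per NADH under an oxygen bound), short-chain-equivalent
β-oxidation (3 acetyl-CoA per fatty-acid unit), malonyl-CoA-dependent
palmitoleate synthesis, acetoacetate formation, pooled amino-acid
catabolism with a urea byproduct, and an NADPH-generating glutamine route
with a glutamate byproduct.

Three structural choices matter for the downstream statistics and are
design decisions of the fixture, not accidents:

* a shared transporter-capacity pool caps total carbon uptake, so sampled
  uptakes concentrate well inside their exchange bounds and are mutually
  coupled, as in a genome-scale model where internal bottlenecks, not
  exchange caps, shape the flux distribution;
* a maintenance ATP window (28–32) pins total catabolic throughput, so
  boundary fluxes cannot dissipate freely into CO2 and a held-out exchange
  is informative about the rest;
* obligate byproducts (methylglyoxal from glycolysis, urea from amino-acid
  catabolism, glutamate from the glutamine route) give each carbon source
  a measured 1:1 reporter, which is what makes leave-one-out validation
  meaningful on a network this small. The oxygen bound is deliberately
  generous so catabolic task capacities are carbon-limited, not
  respiration-limited.

The 12-task catalog spans three designed activity archetypes — glycolytic
(glucose-driven), catabolic (fatty-acid/amino-acid-driven) and redox
(glutamine-driven) — so that task-row clustering at k = 3 has a planted
truth.

The two-profile contextualization design (`two_phenotype_fold_changes()`)
contrasts a glycolysis-dominant plasma profile (glucose, lactate,
methylglyoxal about 2-fold up) with a catabolism-dominant one (fatty-acid,
amino-acid, urea, succinate up; glucose, glutamine down). The fold changes
within each profile are chosen to be approximately realizable by a single
steady state of the toy network (e.g. the succinate elevation is kept at
2.2-fold, within the carbon the profile supplies), because a plasma
profile that no flux state can honour would make the cross-validation
measure the design's inconsistency rather than the method's accuracy. On
this design the glycolytic-ATP and lactate-from-glucose ratios
(glycolytic/catabolic model) are > 1, and the malonyl-CoA-synthesis and
TCA-NADH ratios are < 1: in a pure capacity model, elevated fatty-acid and
amino-acid supply means more acetyl-CoA and therefore more malonyl-CoA
headroom, which is the expected direction for this design even though
regulated cells can invert it.

# Problem sizes and determinism

Default experiment sizes — 1000–1500 flux samples for baseline quartiles,
400–500 per leave-one-out model, 99 + 20 synthetic subjects, 2000-patient
cohorts for survival calibration — were chosen so the complete test suite
and the analysis workflow run comfortably on a laptop-class single core
while keeping Monte-Carlo error well inside the tolerances asserted.
Every stochastic function takes a mandatory seed; identical seeds give
bit-identical outputs, including the sampler and the imputation forests.

# Known limitations

* The toy network is a capacity model: no regulation, no thermodynamics,
  no gene–protein–reaction logic, lumped stoichiometry that conserves
  neither carbon nor redox exactly. Directions of task contrasts are
  meaningful; magnitudes are not transferable to a genome-scale model.
* The relaxation log records minimal L1 widenings, which need not be the
  unique minimal certificate when alternative slack distributions tie.
* Hit-and-run mixing is adequate for the toy polytope; genome-scale
  polytopes would need a modern coordinate sampler and far more thinning.
* The significance direction of the validation t-test is reported, not
  interpreted: agreement vs difference is a convention the user must fix.
* Survival simulation is constant-hazard; clinical covariates are drawn
  independently given the phenotype, so multivariate clinical structure
  (e.g. ISS–GCS correlation) is absent.
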