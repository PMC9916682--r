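#!/usr/bin/env Rscript
# Stage 1 — generate every input the pipeline consumes: the synthetic
# trauma + healthy cohort (concentrations, clinical covariates, survival),
# the toy endothelial-like network, the metabolic-task catalog, and the
# metabolite-to-exchange mapping.

library(shinegem)

seed <- 1L
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(seed = seed)
cohort <- simulate_cohort(spec)
files <- write_cohort(cohort, "results/cohort")
write.csv(data.frame(sample_id = names(cohort$phenotype),
                     true_phenotype = unname(cohort$phenotype),
                     planted_outlier = names(cohort$phenotype) %in%
                       cohort$outliers),
          "results/cohort/truth.csv", row.names = FALSE)

net <- build_toy_ecgem()
write_network(net, "results/inputs/toy_ecgem.json")
write_task_catalog(build_toy_task_catalog(),
                   "results/inputs/task_catalog.csv")
write.csv(toy_exchange_mapping(), "results/inputs/exchange_mapping.csv",
          row.names = FALSE)

frac <- colMeans(is.na(cohort$concentrations))
cat("cohort:", nrow(cohort$concentrations), "samples x",
    ncol(cohort$concentrations), "metabolites;",
    sum(cohort$samples$type == "patient"), "patients,",
    sum(cohort$samples$type == "healthy"), "healthy\n")
cat("metabolites with >30% missingness:", sum(frac > 0.30), "\n")
cat("planted outliers:", paste(cohort$outliers, collapse = ", "), "\n")
cat("toy network:", nrow(net$metabolites), "metabolites,",
    nrow(net$reactions), "reactions; feasible:",
    check_feasibility(net)$feasible, "\n")
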