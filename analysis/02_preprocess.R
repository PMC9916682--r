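#!/usr/bin/env Rscript
# Stage 2 — preprocessing: drop metabolites with >30% missingness, impute
# the rest with the iterative tree ensemble, log2 + Pareto scale, remove
# perfect correlates, and flag multivariate outliers on the PCA score
# planes.

library(shinegem)

conc <- read_concentrations("results/cohort/concentrations.csv")
pp <- preprocess_concentrations(conc, seed = 2L)

write.csv(data.frame(sample_id = rownames(pp$normalized), pp$normalized,
                     check.names = FALSE),
          "results/normalized.csv", row.names = FALSE)
write.csv(data.frame(sample_id = rownames(pp$imputed), pp$imputed,
                     check.names = FALSE),
          "results/imputed_raw.csv", row.names = FALSE)
write_preprocess_report(pp$report, "results/preprocess_report.json")

cat("excluded for missingness:",
    paste(pp$report$excluded_metabolites, collapse = ", "), "\n")
cat("imputed cells:", pp$report$imputed_cells, "\n")
cat("perfect correlates dropped:",
    paste(pp$report$dropped_correlates, collapse = ", "), "\n")
cat("outliers removed:", paste(pp$report$outliers, collapse = ", "), "\n")
cat("final matrix:", nrow(pp$normalized), "samples x",
    ncol(pp$normalized), "metabolites\n")
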