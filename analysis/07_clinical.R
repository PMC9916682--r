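#!/usr/bin/env Rscript
# Stage 7 — clinical report: per-phenotype summary table (median [IQR] /
# n (%)), D-versus-rest group tests, EoT rates, Kaplan-Meier curves, and
# the reference-count headline rates.

library(shinegem)

clinical <- read.csv("results/cohort/clinical.csv")
phenos <- read.csv("results/phenotypes.csv")
clinical <- merge(clinical[, setdiff(names(clinical), "phenotype")],
                  phenos, by = "sample_id")

summary_tab <- summarize_cohort(
  clinical, variables = c("iss", "gcs", "sbp", "lactate", "glucose",
                          "epinephrine", "norepinephrine", "syndecan1",
                          "stm", "transfused_4h", "eot", "death"))
write.csv(summary_tab, "results/clinical_summary.csv", row.names = FALSE)

km <- km_estimate(clinical$survival_day, clinical$death,
                  group = clinical$phenotype)
km_df <- do.call(rbind, lapply(names(km), function(g)
  data.frame(phenotype = g, km[[g]])))
write.csv(km_df, "results/km_curves.csv", row.names = FALSE)

cat("30-day survival by phenotype:\n")
for (g in names(km))
  cat(sprintf("  %s: S(30) = %.3f\n", g, km_surv_at(km[[g]], 30)))

cat("\nD-vs-rest tests:\n")
for (v in c("iss", "lactate", "syndecan1", "epinephrine")) {
  gt <- group_tests(clinical[[v]], clinical$phenotype)
  cat(sprintf("  %s: H = %.2f, p = %.2g\n", v, gt$statistic, gt$p_value))
}
eot_gt <- group_tests(ifelse(clinical$eot, "yes", "no"),
                      clinical$phenotype)
cat(sprintf("  EoT: chi-square = %.2f, p = %.2g\n",
            eot_gt$statistic, eot_gt$p_value))

cat("\nreference headline rates (%):\n")
print(round(phenotype_outcome_rates(), 1))
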