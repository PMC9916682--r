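#!/usr/bin/env Rscript
# Stage 3 — phenotype discovery: complete-linkage clustering of the
# preprocessed patient profiles, letter assignment anchored on the
# succinate marker, PLS-DA variable importance, and the phenotype heatmap.

library(shinegem)

norm <- read_concentrations("results/normalized.csv")
truth <- read.csv("results/cohort/truth.csv")
pats <- intersect(rownames(norm), truth$sample_id)  # patients only
pats <- pats[grepl("^P", pats)]

hc <- hier_cluster(norm[pats, ], k = 4)
letters <- assign_phenotype_letters(hc, norm[pats, ], marker = "succinate")
write.csv(data.frame(sample_id = names(letters), phenotype = letters),
          "results/phenotypes.csv", row.names = FALSE)
write_linkage_tree(hc, "results/linkage_tree.json")

vip <- plsda_vip(norm[pats, ], letters, n_components = 2)
write.csv(vip, "results/vip.csv", row.names = FALSE)

render_phenotype_heatmap(norm[pats, ], hc, "results/phenotype_heatmap.png")

tt <- table(letters, truth$true_phenotype[match(pats, truth$sample_id)])
cat("cluster sizes:", paste(names(table(letters)), table(letters),
                            sep = "=", collapse = ", "), "\n")
cat("agreement with planted labels (contingency):\n")
print(tt)
cat("top-5 VIP metabolites:",
    paste(vip$metabolite[1:5], collapse = ", "), "\n")
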