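#!/usr/bin/env Rscript
# Step 5 -- drug-effect profiles and mechanism of action: per line x
# drug logistic regression against DMSO in PC space, AUROC activity
# calls (mean > 0.85), cosine clustering of concatenated effect
# profiles and bottom-up Fisher enrichment of drug targets.

suppressPackageStartupMessages(library(orgprofiler))
dir.create("results", showWarnings = FALSE)
seed <- 2024

tab <- read.csv("results/feature_table.csv")
feat_cols <- c("area", sprintf("morph_%02d", 1:10),
               "dna_int_mean", "dna_int_sd", "dna_tex_energy",
               "actin_int_mean", "actin_int_sd", "actin_tex_energy",
               "perm_int_mean", "perm_int_sd")
drugs <- grep("^moa", unique(tab$treatment), value = TRUE)
targets <- sub("_drug.*$", "", drugs)

profiles <- list()
for (ln in unique(tab$line_id)) {
  i <- tab$line_id == ln
  pca <- fit_pca_transform(as.matrix(tab[i, feat_cols]), n_components = 12)
  for (d in drugs) {
    profiles[[paste(ln, d)]] <-
      fit_drug_effect_profile(pca$scores, tab[i, ], d, seed = seed)
  }
}
calls <- call_active(profiles)
cat(sprintf("active drugs: %d of %d (mean AUROC %.2f-%.2f)\n",
            sum(calls$active), nrow(calls),
            min(calls$mean_auroc), max(calls$mean_auroc)))
write.csv(calls, "results/activity_calls.csv", row.names = FALSE)

active_profiles <- profiles[vapply(profiles, function(p)
  calls$active[calls$drug == p$drug], logical(1))]
tree <- cluster_drug_profiles(active_profiles, method = "cosine")
tree_to_newick(tree, "results/drug_dendrogram.nwk")

ann <- data.frame(drug = drugs, target = sub("_drug.*", "", drugs))
enr <- test_moa_enrichment(tree, ann, min_size = 3)
sig <- enr[enr$fdr < 0.05, ]
cat(sprintf("enriched node x target tests at FDR < 0.05: %d\n", nrow(sig)))
print(head(sig[order(sig$fdr), c("node", "size", "target", "odds_ratio",
                                 "p", "fdr")], 6), row.names = FALSE)
write.csv(enr, "results/moa_enrichment.csv", row.names = FALSE)
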