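#!/usr/bin/env Rscript
# Step 3 -- the phenotype landscape: 25-PC compression of the simulated
# screen, UMAP embedding (min_dist 0.1, 15 neighbours), leiden
# clustering of the embedding, and a dose-dependent principal-curve
# trajectory for the lethal reference compound. Uses a per-line
# subsample to keep the embedding readable.

suppressPackageStartupMessages(library(orgprofiler))
dir.create("results", showWarnings = FALSE)
seed <- 2024

tab <- read.csv("results/feature_table.csv")
feat_cols <- c("area", sprintf("morph_%02d", 1:10),
               "dna_int_mean", "dna_int_sd", "dna_tex_energy",
               "actin_int_mean", "actin_int_sd", "actin_tex_energy",
               "perm_int_mean", "perm_int_sd")
x <- as.matrix(tab[, feat_cols])
x[, "area"] <- log(x[, "area"])   # log-scaled organoid area

set.seed(seed)
sub <- sort(sample(nrow(x), min(6000, nrow(x))))
pca <- fit_pca_transform(x[sub, ], n_components = 10)
em <- embed_umap(pca$scores, min_dist = 0.1, n_neighbors = 15, seed = seed)
em$cluster_labels <- cluster_graph(em$coordinates, resolution = 1e-7,
                                   n_neighbors = 15, seed = seed)
cat(sprintf("embedded %d organoids; leiden clusters: %d\n",
            length(sub), max(em$cluster_labels)))

# dose trajectory of the lethal compound against DMSO
meta <- tab[sub, ]
rows <- which(meta$treatment %in% c("lethal_01", "DMSO") &
                meta$role != "positive_control")
dose <- meta$concentration[rows]
dose[meta$treatment[rows] == "DMSO"] <- 0
tr <- fit_dose_trajectory(em, rows, dose = dose,
                          is_control = meta$treatment[rows] == "DMSO",
                          seed = seed)
med <- tapply(tr$pseudotime, dose, median, na.rm = TRUE)
rho <- cor(rank(as.numeric(names(med))), rank(med))
cat("median pseudotime by dose:\n")
print(round(med, 2))
cat(sprintf("Spearman(dose, median pseudotime) = %.2f\n", rho))

out <- data.frame(organoid_id = meta$organoid_id[rows],
                  treatment = meta$treatment[rows], dose = dose,
                  umap_1 = em$coordinates[rows, 1],
                  umap_2 = em$coordinates[rows, 2],
                  cluster = em$cluster_labels[rows],
                  pseudotime = tr$pseudotime)
write.csv(out, "results/landscape_trajectory.csv", row.names = FALSE)
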