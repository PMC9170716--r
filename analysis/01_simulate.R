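#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic screen used by the downstream steps:
# three organoid lines, the two compound libraries, three mechanism-of-
# action groups with shared shift directions, two lethal reference
# compounds, and line-specific bimodal size mixtures. Writes the plate
# layouts, per-organoid feature table and ground truth under results/.

suppressPackageStartupMessages(library(orgprofiler))
dir.create("results", showWarnings = FALSE)
seed <- 2024

moa <- moa_treatment_config(n_groups = 3, drugs_per_group = 5,
                            magnitude = 3, seed = seed)
# a lethal compound with a dose-dependent death fraction, mirroring
# proteasome-inhibitor positive controls
moa$lethal_01 <- list(shift = rep(0, 10), moa = "lethal",
                      death_fraction = function(conc, max_conc)
                        min(0.95, (conc / max_conc)^0.5))
spec <- data.frame(drug = names(moa),
                   target = vapply(moa, `[[`, character(1), "moa"),
                   concentration = 7.5e-6)
spec <- rbind(spec[rep(seq_len(nrow(spec) - 1), each = 1), ],
              data.frame(drug = "lethal_01", target = "lethal",
                         concentration = 2.5e-6 / 5^(4:0)))

layout <- generate_plate_layout(n_lines = 3, spec, seed = seed)
sim <- simulate_feature_table(layout, effect_config(treatments = moa,
                                                    organoids_per_well = 40),
                              seed = seed + 1)

write.csv(layout, "results/plate_layout.csv", row.names = FALSE)
write.csv(cbind(sim$fm$meta, sim$fm$x), "results/feature_table.csv",
          row.names = FALSE)
write.csv(sim$truth$organoids, "results/ground_truth_organoids.csv",
          row.names = FALSE)

cat(sprintf("simulated %d organoids across %d wells, %d lines\n",
            nrow(sim$fm$x), nrow(layout),
            length(unique(layout$line_id))))
cat(sprintf("dead organoids: %.1f%%\n",
            100 * mean(sim$truth$organoids$true_dead)))
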