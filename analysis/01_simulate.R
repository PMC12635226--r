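#!/usr/bin/env Rscript
# Stage 1: simulate the study conditions.
#
# One dataset with planted biology: three stromal subsets, 200 cells per
# (subset, age group), two ligand-receptor effects up-regulated 4-fold in
# the old group (PLAU->PLAUR within MSC; IL6->IL6ST from MSC to
# adipocyte1), 12 planted low-quality cells, and 30 decoy pairs. A second,
# effect-free dataset provides the exchangeable-label null.

suppressPackageStartupMessages(library(agecrosstalk))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[[1]] == "--seed")
  args[[2]] else 20240901)

effects <- rbind(
  planted_effect("PLAU", "PLAUR", "MSC", "MSC", "old", 4),
  planted_effect("IL6", "IL6ST", "MSC", "adipocyte1", "old", 4)
)
planted_cfg <- sim_config(
  n_subsets = 3, cells_per_subset_per_age = 200,
  n_genes = 500, n_mito_genes = 13,
  planted_effects = effects,
  n_lowquality_cells = 12, n_decoy_pairs = 30,
  seed = seed
)
planted <- generate_dataset(planted_cfg)
write_dataset(planted, "results/data/planted")

null_cfg <- sim_config(
  n_subsets = 3, cells_per_subset_per_age = 100,
  n_genes = 400, n_mito_genes = 10, n_decoy_pairs = 56,
  seed = seed + 1L
)
nulld <- make_null_dataset(null_cfg)
write_dataset(nulld, "results/data/null")

cat(sprintf("planted dataset: %d genes x %d cells, %d LR pairs (%d planted, %d decoys), %d low-quality cells\n",
            nrow(planted$matrix), ncol(planted$matrix),
            nrow(planted$lr_table),
            sum(planted$lr_table$source == "planted"),
            sum(planted$lr_table$source == "decoy"),
            length(planted$truth$lowquality_cells)))
cat(sprintf("null dataset: %d genes x %d cells, %d decoy pairs\n",
            nrow(nulld$matrix), ncol(nulld$matrix), nrow(nulld$lr_table)))
cat("written under results/data/{planted,null}\n")
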