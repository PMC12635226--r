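#!/usr/bin/env Rscript
# Stage 5: statistical validation of the permutation test.
#
# (a) On the effect-free null dataset, the fraction of interactions with
#     p <= 0.01 should sit in the 99% binomial band around the nominal
#     level (the unshifted p = n/N flags at ~(floor(0.01 N)+1)/(N+1)).
# (b) On a tiny instance the Monte-Carlo p-values are compared with the
#     exact values from exhaustive enumeration of all 36 within-subset
#     label arrangements.

suppressPackageStartupMessages(library(agecrosstalk))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[[1]] == "--seed")
  args[[2]] else 20240901)

mat <- read_matrix("results/data/null/matrix.mtx",
                   "results/data/null/features.tsv",
                   "results/data/null/barcodes.tsv")
ann <- read_annotation("results/data/null/annotation.tsv")
lr <- read_lr_table("results/data/null/lr_pairs.tsv")
cfg <- analysis_config(n_permutations = 1000, seed = seed + 2L)

null_p <- run_crosstalk(mat, ann, lr, cfg)$interactions$p
frac <- mean(null_p <= 0.01)
band <- stats::qbinom(c(0.005, 0.995), length(null_p), 0.01) / length(null_p)
cat(sprintf("null significant fraction at alpha 0.01: %.4f over %d interactions (99%% band %.4f-%.4f)\n",
            frac, length(null_p), band[[1]], band[[2]]))

toy <- generate_dataset(sim_config(
  n_subsets = 2, cells_per_subset_per_age = 2, n_genes = 25,
  n_mito_genes = 2, n_decoy_pairs = 5,
  planted_effects = planted_effect("L1", "R1", "MSC", "adipocyte1",
                                   "old", 4),
  seed = seed + 3L
))
toy_cfg <- analysis_config(n_permutations = 10000, seed = seed + 4L)
exact <- exact_crosstalk_pvalues(toy$matrix, toy$annotation, toy$lr_table,
                                 toy_cfg)
mc <- run_crosstalk(toy$matrix, toy$annotation, toy$lr_table,
                    toy_cfg)$interactions
key <- function(x) paste(x$ligand, x$receptor, x$sender, x$receiver,
                         x$age_group)
exact <- exact[match(key(mc), key(exact)), ]
dev <- max(abs(mc$p - exact$p_exact))
cat(sprintf("max |Monte-Carlo - exact| over %d toy interactions: %.4f (N = 10000, 36 arrangements)\n",
            nrow(mc), dev))

dir.create("results", showWarnings = FALSE)
write_result_table(
  data.frame(check = c("null_sig_fraction_alpha01", "mc_exact_max_abs_diff"),
             value = c(frac, dev),
             n = c(length(null_p), nrow(mc))),
  "results/calibration.tsv", cfg)
cat("calibration.tsv written under results/\n")
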