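#!/usr/bin/env Rscript
# Stage 3: differential expression on the QC'd data.
#
# Cluster markers (group-vs-rest Wilcoxon, Bonferroni-corrected p < 0.01
# and fold change > 1.5) and aging-associated genes per subset
# (old-vs-young Wilcoxon, raw p < 0.05 with Benjamini-Hochberg values
# reported). The planted ligands should surface among the old-shifted
# genes of their sender subsets.

suppressPackageStartupMessages(library(agecrosstalk))

mat <- read_matrix("results/qc/matrix.mtx", "results/qc/features.tsv",
                   "results/qc/barcodes.tsv")
ann <- read_annotation("results/qc/annotation.tsv")
cfg <- analysis_config()
norm <- normalize_counts(mat, cfg$normalization)

markers <- find_markers(norm, ann, config = cfg)
cat(sprintf("markers: %d flagged of %d (gene, subset) tests\n",
            sum(markers$flagged), nrow(markers)))

aging <- do.call(rbind, lapply(unique(ann$subset), function(s)
  aging_genes(norm, ann, s, config = cfg)))
cat(sprintf("aging-associated genes: %d flagged of %d tests\n",
            sum(aging$flagged), nrow(aging)))
planted_rows <- aging[aging$gene %in% c("PLAU", "IL6") &
                        aging$subset == "MSC", ]
print(planted_rows, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write_result_table(markers, "results/markers.tsv", cfg)
write_result_table(aging, "results/aging_genes.tsv", cfg)
cat("markers.tsv and aging_genes.tsv written under results/\n")
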