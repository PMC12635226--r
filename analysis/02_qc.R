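#!/usr/bin/env Rscript
# Stage 2: quality control on the planted dataset.
#
# Removes cells with fewer than 200 detected genes or more than 10%
# mitochondrial counts, then genes expressed in fewer than 3 surviving
# cells, and checks that exactly the planted low-quality cells fell out.

suppressPackageStartupMessages(library(agecrosstalk))

mat <- read_matrix("results/data/planted/matrix.mtx",
                   "results/data/planted/features.tsv",
                   "results/data/planted/barcodes.tsv")
ann <- read_annotation("results/data/planted/annotation.tsv")
lq <- readLines("results/data/planted/truth_lowquality_cells.tsv")

res <- apply_qc(mat, ann, analysis_config())
print(res$report)

removed <- res$report$removed_cells$cell_id
cat(sprintf("planted low-quality cells removed: %d of %d\n",
            sum(lq %in% removed), length(lq)))
extra <- setdiff(removed, lq)
cat(sprintf("additional cells removed by the thresholds: %d\n",
            length(extra)))

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write_matrix(res$matrix, "results/qc")
write_annotation(res$annotation, "results/qc/annotation.tsv")
write_qc_report(res$report, "results/qc/qc_report.tsv")
cat("filtered matrix and qc_report.tsv written under results/qc\n")
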