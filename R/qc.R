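#' Genes detected per cell
#'
#' Number of genes with a nonzero count in each cell.
#'
#' @param mat Raw counts matrix (genes x cells).
#' @return Integer vector, one entry per cell.
#' @export
detect_genes_per_cell <- function(mat) {
  assert_expression_matrix(mat)
  n <- as.integer(Matrix::colSums(mat > 0))
  names(n) <- colnames(mat)
  n
}

#' Mitochondrial count fraction per cell
#'
#' Share of a cell's total counts on genes matching `mito_pattern`.
#' All-zero cells get 0; if no gene matches, every fraction is 0 with a
#' warning.
#'
#' @param mat Raw counts matrix (genes x cells).
#' @param mito_pattern Regular expression matched against gene names.
#' @return Numeric vector in `[0, 1]`, one entry per cell.
#' @export
mito_fraction <- function(mat, mito_pattern = "^MT-") {
  assert_expression_matrix(mat)
  is_mito <- grepl(mito_pattern, rownames(mat))
  if (!any(is_mito) && nrow(mat) > 0) {
    warning("no gene matches mito_pattern '", mito_pattern, "'",
            call. = FALSE)
  }
  totals <- Matrix::colSums(mat)
  mito <- Matrix::colSums(mat[is_mito, , drop = FALSE])
  frac <- ifelse(totals > 0, mito / totals, 0)
  names(frac) <- colnames(mat)
  frac
}

#' Apply cell- and gene-level quality control
#'
#' Cell filters first: a cell is removed when it has fewer than
#' `min_genes_per_cell` detected genes or more than `max_mito_fraction`
#' mitochondrial counts (strict inequalities, so boundary cells are kept;
#' `qc_rule = "intersection"` requires both failures). Then genes expressed
#' in fewer than `min_cells_per_gene` of the surviving cells are removed.
#' One pass, no iteration.
#'
#' @param mat Raw counts matrix (genes x cells).
#' @param annotation Cell annotation covering every cell in `mat`.
#' @param config An [analysis_config()] carrying the thresholds.
#' @return A list with `matrix` and `annotation` (filtered) and `report`,
#'   a `qc_report` recording sizes, removed cells with their reason
#'   (`low_genes`, `high_mito`, `both`), removed genes, and the thresholds
#'   applied.
#' @export
apply_qc <- function(mat, annotation, config = analysis_config()) {
  assert_expression_matrix(mat, require_raw = TRUE)
  annotation <- align_annotation(annotation, mat)

  n_detected <- detect_genes_per_cell(mat)
  mfrac <- mito_fraction(mat, config$mito_pattern)
  low_genes <- n_detected < config$min_genes_per_cell
  high_mito <- mfrac > config$max_mito_fraction
  drop_cell <- if (config$qc_rule == "union") low_genes | high_mito
               else low_genes & high_mito

  removed_cells <- data.frame(
    cell_id = colnames(mat)[drop_cell],
    reason = ifelse(low_genes[drop_cell] & high_mito[drop_cell], "both",
                    ifelse(low_genes[drop_cell], "low_genes", "high_mito")),
    stringsAsFactors = FALSE
  )

  kept <- mat[, !drop_cell, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(kept > 0)
  drop_gene <- cells_per_gene < config$min_cells_per_gene
  removed_genes <- rownames(kept)[drop_gene]

  out <- kept[!drop_gene, , drop = FALSE]
  expression_layer(out) <- "raw"
  report <- structure(list(
    n_cells_in = ncol(mat), n_cells_out = ncol(out),
    n_genes_in = nrow(mat), n_genes_out = nrow(out),
    removed_cells = removed_cells,
    removed_genes = removed_genes,
    thresholds = list(min_genes_per_cell = config$min_genes_per_cell,
                      max_mito_fraction = config$max_mito_fraction,
                      min_cells_per_gene = config$min_cells_per_gene,
                      qc_rule = config$qc_rule)
  ), class = "qc_report")

  list(matrix = out,
       annotation = annotation[!drop_cell, , drop = FALSE],
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality-control report\n")
  cat(sprintf("  cells: %d -> %d (%d removed)\n", x$n_cells_in, x$n_cells_out,
              nrow(x$removed_cells)))
  if (nrow(x$removed_cells)) {
    tab <- table(x$removed_cells$reason)
    cat(sprintf("    %s: %d\n", names(tab), as.integer(tab)), sep = "")
  }
  cat(sprintf("  genes: %d -> %d (%d removed, expressed in < %d cells)\n",
              x$n_genes_in, x$n_genes_out, length(x$removed_genes),
              x$thresholds$min_cells_per_gene))
  invisible(x)
}

#' Write a QC report as a table
#'
#' One row per removed cell or gene with axis and reason, preceded by
#' commented summary lines.
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  n_g <- length(report$removed_genes)
  rows <- rbind(
    data.frame(axis = rep("cell", nrow(report$removed_cells)),
               id = report$removed_cells$cell_id,
               reason = report$removed_cells$reason,
               stringsAsFactors = FALSE),
    data.frame(axis = rep("gene", n_g), id = report$removed_genes,
               reason = rep("low_prevalence", n_g),
               stringsAsFactors = FALSE)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# cells_in: %d", report$n_cells_in), con)
  writeLines(sprintf("# cells_out: %d", report$n_cells_out), con)
  writeLines(sprintf("# genes_in: %d", report$n_genes_in), con)
  writeLines(sprintf("# genes_out: %d", report$n_genes_out), con)
  writeLines(sprintf("# %s: %s", names(report$thresholds),
                     vapply(report$thresholds, format, character(1))), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
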