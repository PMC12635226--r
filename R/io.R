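#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one place, at the
#' defaults used throughout: 1000 permutations with significance at
#' p <= 0.01 for crosstalk; Bonferroni-corrected p < 0.01 and fold change
#' > 1.5 for cluster markers; raw p < 0.05 (Benjamini-Hochberg values also
#' reported) for aging-associated genes; quality control keeps cells with at
#' least 200 detected genes and at most 10% mitochondrial counts, and genes
#' expressed in at least 3 surviving cells.
#'
#' @param n_permutations Number of label permutations for the crosstalk null.
#' @param alpha_crosstalk Significance cutoff on the permutation p-value
#'   (interactions with `p <= alpha_crosstalk` are flagged).
#' @param marker_alpha Cutoff on the Bonferroni-corrected marker p-value.
#' @param marker_fc Linear fold-change cutoff for markers (strictly greater).
#' @param aging_gene_alpha Cutoff for aging-associated genes.
#' @param aging_use_adjusted Flag aging genes on the Benjamini-Hochberg value
#'   instead of the raw p-value.
#' @param min_genes_per_cell Cells with fewer detected genes are removed.
#' @param max_mito_fraction Cells with a larger mitochondrial count fraction
#'   are removed.
#' @param min_cells_per_gene Genes expressed in fewer surviving cells are
#'   removed.
#' @param qc_rule `"union"` removes a cell failing either cell-level filter;
#'   `"intersection"` removes only cells failing both.
#' @param mito_pattern Regular expression identifying mitochondrial genes.
#' @param normalization Expression scale used for crosstalk scoring and
#'   differential expression: `"raw"`, `"cp10k"` (counts per 10,000) or
#'   `"log1p_cp10k"`.
#' @param fc_mode Fold-change scale for markers: `"linear_ratio"` or
#'   `"log2_diff"`.
#' @param report_pseudo_p Also report the bias-corrected permutation p-value
#'   (n+1)/(N+1) alongside n/N.
#' @param seed Integer seed driving every random draw of a run.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_permutations = 1000,
                            alpha_crosstalk = 0.01,
                            marker_alpha = 0.01,
                            marker_fc = 1.5,
                            aging_gene_alpha = 0.05,
                            aging_use_adjusted = FALSE,
                            min_genes_per_cell = 200,
                            max_mito_fraction = 0.10,
                            min_cells_per_gene = 3,
                            qc_rule = c("union", "intersection"),
                            mito_pattern = "^MT-",
                            normalization = c("cp10k", "raw", "log1p_cp10k"),
                            fc_mode = c("linear_ratio", "log2_diff"),
                            report_pseudo_p = FALSE,
                            seed = 1L) {
  stopifnot(
    n_permutations >= 1,
    alpha_crosstalk > 0, alpha_crosstalk < 1,
    marker_alpha > 0, marker_alpha < 1,
    aging_gene_alpha > 0, aging_gene_alpha < 1,
    marker_fc > 0,
    min_genes_per_cell >= 0,
    max_mito_fraction >= 0, max_mito_fraction <= 1,
    min_cells_per_gene >= 0
  )
  structure(list(
    n_permutations = as.integer(n_permutations),
    alpha_crosstalk = alpha_crosstalk,
    marker_alpha = marker_alpha,
    marker_fc = marker_fc,
    aging_gene_alpha = aging_gene_alpha,
    aging_use_adjusted = isTRUE(aging_use_adjusted),
    min_genes_per_cell = as.integer(min_genes_per_cell),
    max_mito_fraction = max_mito_fraction,
    min_cells_per_gene = as.integer(min_cells_per_gene),
    qc_rule = match.arg(qc_rule),
    mito_pattern = mito_pattern,
    normalization = match.arg(normalization),
    fc_mode = match.arg(fc_mode),
    report_pseudo_p = isTRUE(report_pseudo_p),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read a genes-by-cells matrix from a MatrixMarket triplet
#'
#' Reads the CellRanger-style on-disk layout: a coordinate MatrixMarket file
#' plus one-column sidecar files listing gene and cell identifiers (first
#' tab-separated field of each line, no header). The returned matrix is
#' oriented genes x cells; set `transpose = TRUE` when the file stores cells
#' as rows.
#'
#' @param path_matrix Path to the `.mtx` file.
#' @param path_features Path to the gene-id sidecar (one gene per line).
#' @param path_barcodes Path to the cell-id sidecar (one cell per line).
#' @param transpose Transpose the on-disk matrix after reading.
#'
#' @return A sparse `dgCMatrix` with gene rownames and cell colnames, tagged
#'   as the raw layer.
#' @export
read_matrix <- function(path_matrix, path_features, path_barcodes,
                        transpose = FALSE) {
  mat <- Matrix::readMM(path_matrix)
  if (transpose) mat <- Matrix::t(mat)
  features <- read_id_column(path_features)
  barcodes <- read_id_column(path_barcodes)
  if (length(features) != nrow(mat)) {
    stop("'", path_features, "' lists ", length(features),
         " genes but '", path_matrix, "' declares ", nrow(mat), " rows",
         call. = FALSE)
  }
  if (length(barcodes) != ncol(mat)) {
    stop("'", path_barcodes, "' lists ", length(barcodes),
         " cells but '", path_matrix, "' declares ", ncol(mat), " columns",
         call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("duplicate gene ids in '", path_features, "'", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate cell ids in '", path_barcodes, "'", call. = FALSE)
  }
  if (any(mat@x < 0)) {
    stop("negative values in '", path_matrix, "'", call. = FALSE)
  }
  mat <- methods::as(mat, "CsparseMatrix")
  dimnames(mat) <- list(features, barcodes)
  expression_layer(mat) <- "raw"
  mat
}

read_id_column <- function(path) {
  lines <- readLines(path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a genes-by-cells matrix as a MatrixMarket triplet
#'
#' @param mat Matrix with gene rownames and cell colnames.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return Invisibly, the three paths written.
#' @export
write_matrix <- function(mat, dir) {
  assert_expression_matrix(mat)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(methods::as(mat, "dMatrix"), "TsparseMatrix"),
                  paths[[1]])
  writeLines(rownames(mat), paths[[2]])
  writeLines(colnames(mat), paths[[3]])
  invisible(paths)
}

#' Read / write a cell annotation table
#'
#' Tab-separated with header columns `cell_id`, `subset`, `age_group`;
#' `age_group` must take exactly two values across the table (young/old).
#'
#' @param path File path.
#' @return A data.frame with one row per cell.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", comment.char = "#")
  assert_annotation(ann)
  n_ages <- length(unique(ann$age_group))
  if (n_ages != 2) {
    stop("'", path, "' has ", n_ages, " age group level(s); expected 2",
         call. = FALSE)
  }
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  assert_annotation(annotation)
  write.table(annotation[c("cell_id", "subset", "age_group")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Tab-separated with a header containing `ligand` and `receptor` columns
#' (a `source` column is kept when present). Pairs are ordered: A -> B and
#' B -> A are distinct interactions. Exact duplicate (ligand, receptor)
#' rows are collapsed with a warning.
#'
#' @param path File path.
#' @return A data.frame with columns `ligand`, `receptor`, `source`.
#' @export
read_lr_table <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", comment.char = "#")
  missing <- setdiff(c("ligand", "receptor"), names(tab))
  if (length(missing)) {
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"source" %in% names(tab)) tab$source <- "user"
  tab <- tab[c("ligand", "receptor", "source")]
  if (nrow(tab) && any(!nzchar(tab$ligand) | !nzchar(tab$receptor))) {
    stop("'", path, "' contains empty gene ids", call. = FALSE)
  }
  dup <- duplicated(tab[c("ligand", "receptor")])
  if (any(dup)) {
    warning(sum(dup), " duplicate ligand-receptor pair(s) collapsed",
            call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Packaged ligand-receptor pairs
#'
#' The interactions highlighted in aging thymic stroma work (PLAU-PLAUR,
#' IL1B-IL1R1, IL6-IL6ST, collagen/fibronectin-integrin pairs, HAS2-CD44,
#' IGF2-INSR, LPL-VLDLR, APOE-LDLR, ...), shipped as a ready-to-use table.
#'
#' @return A data.frame with columns `ligand`, `receptor`, `source`.
#' @export
default_lr_table <- function() {
  read_lr_table(system.file("extdata", "lr_pairs_aging_thymus.tsv",
                            package = "agecrosstalk", mustWork = TRUE))
}

#' @rdname read_lr_table
#' @param lr_table Pair table as returned by [read_lr_table()].
#' @export
write_lr_table <- function(lr_table, path) {
  write.table(lr_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a raw counts matrix
#'
#' `cp10k` scales every cell (column) to a total of 10,000 counts;
#' `log1p_cp10k` additionally applies `log(x + 1)`; `raw` is the identity.
#' All-zero cells are left all-zero with a warning.
#'
#' @param mat Raw counts matrix (genes x cells).
#' @param mode One of `"raw"`, `"cp10k"`, `"log1p_cp10k"`.
#' @return The rescaled matrix, tagged with its new layer.
#' @export
normalize_counts <- function(mat, mode = c("cp10k", "raw", "log1p_cp10k")) {
  mode <- match.arg(mode)
  assert_expression_matrix(mat, require_raw = TRUE)
  if (mode == "raw") return(mat)
  totals <- Matrix::colSums(mat)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) left unscaled", call. = FALSE)
    totals[zero] <- 1
  }
  out <- mat %*% Matrix::Diagonal(x = 10000 / totals)
  dimnames(out) <- dimnames(mat)
  if (mode == "log1p_cp10k") out <- log1p(out)
  out <- methods::as(out, "CsparseMatrix")
  expression_layer(out) <- mode
  out
}

#' Write a result table with an audit header
#'
#' Tab-separated table preceded by `#`-commented lines recording the
#' software version, seed and thresholds of the run, so permutation results
#' stay traceable to their configuration.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param config `analysis_config` of the run (optional).
#' @export
write_result_table <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# agecrosstalk %s",
                     as.character(utils::packageVersion("agecrosstalk"))), con)
  if (!is.null(config)) {
    scalars <- Filter(function(x) is.atomic(x) && length(x) == 1L,
                      unclass(config))
    writeLines(sprintf("# %s: %s", names(scalars),
                       vapply(scalars, format, character(1))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#")
}
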