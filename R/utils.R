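#' @importFrom Matrix colSums rowSums t readMM writeMM sparseMatrix
#' @importFrom methods as is
#' @importFrom stats rnbinom rlnorm wilcox.test p.adjust
#' @importFrom utils read.delim write.table combn
NULL

# Run `code` under a fixed RNG state and restore the caller's state after.
# RNG kinds are pinned so results are identical across fresh sessions.
with_rng_seed <- function(seed, code) {
  withr::with_seed(
    seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Expression layer bookkeeping: a matrix is tagged with the scale its values
# are on ("raw", "cp10k", "log1p_cp10k"). Untagged matrices count as raw.
expression_layer <- function(x) {
  tag <- attr(x, "expression_layer")
  if (is.null(tag)) "raw" else tag
}

`expression_layer<-` <- function(x, value) {
  value <- match.arg(value, c("raw", "cp10k", "log1p_cp10k"))
  attr(x, "expression_layer") <- value
  x
}

assert_expression_matrix <- function(mat, require_raw = FALSE) {
  if ((nrow(mat) > 0 && is.null(rownames(mat))) ||
      (ncol(mat) > 0 && is.null(colnames(mat)))) {
    stop("expression matrix must carry gene rownames and cell colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate cell ids in expression matrix", call. = FALSE)
  }
  if (require_raw && expression_layer(mat) != "raw") {
    stop("operation requires the raw counts layer, got '",
         expression_layer(mat), "'", call. = FALSE)
  }
  invisible(mat)
}

assert_annotation <- function(annotation, mat = NULL) {
  required <- c("cell_id", "subset", "age_group")
  missing <- setdiff(required, names(annotation))
  if (length(missing)) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotation$cell_id)) {
    stop("annotation has duplicated cell_id values", call. = FALSE)
  }
  if (!is.null(mat)) {
    unannotated <- setdiff(colnames(mat), annotation$cell_id)
    if (length(unannotated)) {
      stop(length(unannotated), " cell(s) in the matrix lack annotation, e.g. ",
           unannotated[[1]], call. = FALSE)
    }
  }
  invisible(annotation)
}

# Annotation rows in matrix column order.
align_annotation <- function(annotation, mat) {
  assert_annotation(annotation, mat)
  annotation[match(colnames(mat), annotation$cell_id), , drop = FALSE]
}
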