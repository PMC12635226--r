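#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with midrank tie handling: the p-value comes from exact
#' enumeration when both groups have at most 8 observations and no ties are
#' present, and from the normal approximation with tie correction
#' otherwise.
#'
#' @param values_a,values_b Nonempty numeric vectors.
#' @return A list with `statistic` (the Mann-Whitney U of group a) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Multiple-testing corrections
#'
#' `bonferroni()` returns `min(1, m * p)`; `benjamini_hochberg()` the
#' step-up false-discovery-rate values, clipped to `[0, 1]` and monotone
#' over the ranked p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bonferroni <- function(p) {
  assert_pvalues(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' @rdname bonferroni
#' @export
benjamini_hochberg <- function(p) {
  assert_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

assert_pvalues <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# Means on the linear expression scale, de-logging first when the layer is
# log-transformed; used for fold changes and directions.
linear_means <- function(mat, cols) {
  m <- Matrix::rowSums(mat[, cols, drop = FALSE]) / sum(cols)
  if (expression_layer(mat) == "log1p_cp10k") {
    # de-log per value, then average
    m <- Matrix::rowSums(expm1(mat[, cols, drop = FALSE])) / sum(cols)
  }
  m
}

#' Cluster marker detection
#'
#' Group-versus-rest Wilcoxon rank-sum test per gene, Bonferroni-corrected
#' across the genes tested within a group. The fold change is the ratio of
#' linear-scale mean expression in the group over the rest (pseudocount
#' 1e-9), or the log2 mean difference when `fc_mode = "log2_diff"`. A gene
#' is flagged as a marker when the corrected p-value is below
#' `marker_alpha` and the fold change exceeds `marker_fc`.
#'
#' @param mat Normalized expression matrix (genes x cells).
#' @param annotation Cell annotation covering every cell.
#' @param groups Subset labels to test (default: all).
#' @param config An [analysis_config()].
#' @return A data.frame with one row per (gene, group): `gene`, `group`,
#'   `p_raw`, `p_adj`, `fold_change`, `flagged`.
#' @export
find_markers <- function(mat, annotation, groups = NULL,
                         config = analysis_config()) {
  assert_expression_matrix(mat)
  annotation <- align_annotation(annotation, mat)
  if (is.null(groups)) groups <- unique(annotation$subset)
  missing <- setdiff(groups, annotation$subset)
  if (length(missing)) {
    stop("unknown group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eps <- 1e-9
  dense <- as.matrix(mat)
  out <- lapply(groups, function(g) {
    in_group <- annotation$subset == g
    if (sum(in_group) < 2) {
      stop("group '", g, "' has fewer than 2 cells", call. = FALSE)
    }
    p_raw <- apply(dense, 1L, function(v) {
      wilcoxon_test(v[in_group], v[!in_group])$p_value
    })
    mean_in <- linear_means(mat, in_group)
    mean_out <- linear_means(mat, !in_group)
    fc <- if (config$fc_mode == "linear_ratio") {
      (mean_in + eps) / (mean_out + eps)
    } else {
      log2(mean_in + eps) - log2(mean_out + eps)
    }
    p_adj <- bonferroni(p_raw)
    data.frame(gene = rownames(mat), group = g, p_raw = p_raw, p_adj = p_adj,
               fold_change = unname(fc),
               flagged = p_adj < config$marker_alpha & fc > config$marker_fc,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aging-associated gene detection
#'
#' Old-versus-young Wilcoxon rank-sum test per gene within one cell
#' subset. Benjamini-Hochberg values are reported alongside the raw
#' p-values; flagging uses the raw p-value below `aging_gene_alpha` by
#' default (`aging_use_adjusted = TRUE` switches to the BH value).
#' Direction is the sign of the old-minus-young linear mean difference.
#'
#' @param mat Normalized expression matrix (genes x cells).
#' @param annotation Cell annotation covering every cell.
#' @param subset Subset label to test within.
#' @param config An [analysis_config()].
#' @return A data.frame with one row per gene: `gene`, `subset`, `p_raw`,
#'   `p_bh`, `direction` (`up_in_old` / `down_in_old`), `flagged`.
#' @export
aging_genes <- function(mat, annotation, subset,
                        config = analysis_config()) {
  assert_expression_matrix(mat)
  annotation <- align_annotation(annotation, mat)
  in_subset <- annotation$subset == subset
  if (!any(in_subset)) {
    stop("unknown subset '", subset, "'", call. = FALSE)
  }
  old <- in_subset & annotation$age_group == "old"
  young <- in_subset & annotation$age_group == "young"
  if (!any(old) || !any(young)) {
    stop("subset '", subset, "' lacks cells in one age group",
         call. = FALSE)
  }
  dense <- as.matrix(mat)
  p_raw <- apply(dense, 1L, function(v) {
    wilcoxon_test(v[old], v[young])$p_value
  })
  p_bh <- benjamini_hochberg(p_raw)
  delta <- linear_means(mat, old) - linear_means(mat, young)
  p_flag <- if (config$aging_use_adjusted) p_bh else p_raw
  data.frame(
    gene = rownames(mat), subset = subset, p_raw = p_raw, p_bh = p_bh,
    direction = ifelse(delta >= 0, "up_in_old", "down_in_old"),
    flagged = p_flag < config$aging_gene_alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
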