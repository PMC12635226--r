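#' Mean expression of a gene in a (subset, age group) cell block
#'
#' @param mat Expression matrix (genes x cells), any layer.
#' @param annotation Cell annotation covering every cell.
#' @param subset Subset label.
#' @param age_group Age-group label.
#' @param gene Gene id.
#' @return Arithmetic mean of the gene over exactly those cells.
#' @export
group_mean <- function(mat, annotation, subset, age_group, gene) {
  assert_expression_matrix(mat)
  annotation <- align_annotation(annotation, mat)
  if (!gene %in% rownames(mat)) {
    stop("gene '", gene, "' not in matrix", call. = FALSE)
  }
  cells <- annotation$subset == subset & annotation$age_group == age_group
  if (!any(cells)) {
    stop("no cells in (", subset, ", ", age_group, ")", call. = FALSE)
  }
  sum(mat[gene, cells]) / sum(cells)
}

#' Ligand-receptor interaction score
#'
#' The score of an ordered ligand-receptor pair between a sender and a
#' receiver subset, within one age group: the product of the mean ligand
#' expression over sender cells and the mean receptor expression over
#' receiver cells. Zero whenever either mean is zero.
#'
#' @inheritParams group_mean
#' @param ligand,receptor Gene ids.
#' @param sender,receiver Subset labels.
#' @return Non-negative score.
#' @export
interaction_score <- function(mat, annotation, ligand, receptor,
                              sender, receiver, age_group) {
  group_mean(mat, annotation, sender, age_group, ligand) *
    group_mean(mat, annotation, receiver, age_group, receptor)
}

#' Permute age-group labels within each cell subset
#'
#' Uniformly shuffles the multiset of age labels among the cells of every
#' subset independently; per-subset young/old counts and the subset labels
#' themselves are preserved exactly. Subsets carrying only one age group
#' are left unchanged with a warning.
#'
#' @param annotation Cell annotation.
#' @param seed Optional integer; when given, the permutation is drawn
#'   under this seed without disturbing the caller's RNG state.
#' @return The annotation with permuted `age_group`.
#' @export
permute_age_labels <- function(annotation, seed = NULL) {
  assert_annotation(annotation)
  single <- tapply(annotation$age_group, annotation$subset,
                   function(a) length(unique(a)) == 1L)
  if (any(single)) {
    warning("subset(s) with a single age group left unpermuted: ",
            paste(names(single)[single], collapse = ", "), call. = FALSE)
  }
  shuffle <- function() {
    for (s in unique(annotation$subset)) {
      idx <- which(annotation$subset == s)
      if (!single[[s]]) {
        annotation$age_group[idx] <- annotation$age_group[idx][
          sample.int(length(idx))]
      }
    }
    annotation
  }
  if (is.null(seed)) shuffle() else with_rng_seed(seed, shuffle())
}

# ---- internal engine -------------------------------------------------------
#
# All permutation p-values are computed by one vectorized engine. The
# expression submatrix of the ligand/receptor genes is densified; a group
# id (subset x age) is assigned per cell; per iteration ONE joint shuffle
# (an independent within-subset permutation of the age labels of every
# subset) is drawn and shared across all pairs, subset pairs and age
# groups, and group means are recomputed by rowsum.

# cells x genes sums per group, divided by group size -> groups x genes
group_mean_table <- function(tE, gid, n_groups, group_sizes) {
  sums <- rowsum(tE, gid, reorder = FALSE)
  # rowsum orders by first appearance of gid; map rows back to group index
  rows <- as.integer(rownames(sums))
  out <- matrix(0, nrow = n_groups, ncol = ncol(tE))
  out[rows, ] <- sums / group_sizes[rows]
  out
}

crosstalk_engine <- function(E, subset, age, subsets, ages, rec, n_perm,
                             seed) {
  tE <- t(E)
  n_groups <- length(subsets) * length(ages)
  gid0 <- match(subset, subsets) +
    length(subsets) * (match(age, ages) - 1L)
  sizes0 <- tabulate(gid0, n_groups)

  M0 <- group_mean_table(tE, gid0, n_groups, sizes0)
  S <- M0[cbind(rec$cs, rec$li)] * M0[cbind(rec$cr, rec$ri)]

  idx_by_subset <- split(seq_along(subset), factor(subset, levels = subsets))
  n_ge <- integer(nrow(rec))
  with_rng_seed(seed, {
    for (t in seq_len(n_perm)) {
      perm_age <- age
      for (idx in idx_by_subset) {
        perm_age[idx] <- age[idx][sample.int(length(idx))]
      }
      gid <- match(subset, subsets) +
        length(subsets) * (match(perm_age, ages) - 1L)
      Mp <- group_mean_table(tE, gid, n_groups, tabulate(gid, n_groups))
      Sp <- Mp[cbind(rec$cs, rec$li)] * Mp[cbind(rec$cr, rec$ri)]
      n_ge <- n_ge + (Sp >= S)
    }
  })
  list(S = S, n = n_ge, N = n_perm)
}

# Expand records (pair x ordered subset pair x age group) and index them
# against the gene submatrix and the group table.
crosstalk_records <- function(lr_table, gene_ids, subsets, ages) {
  rec <- expand.grid(pair = seq_len(nrow(lr_table)),
                     sender = subsets, receiver = subsets, age_group = ages,
                     stringsAsFactors = FALSE)
  rec$ligand <- lr_table$ligand[rec$pair]
  rec$receptor <- lr_table$receptor[rec$pair]
  rec$li <- match(rec$ligand, gene_ids)
  rec$ri <- match(rec$receptor, gene_ids)
  si <- match(rec$sender, subsets)
  ri <- match(rec$receiver, subsets)
  ai <- match(rec$age_group, ages)
  rec$cs <- si + length(subsets) * (ai - 1L)
  rec$cr <- ri + length(subsets) * (ai - 1L)
  rec
}

prepare_crosstalk_input <- function(mat, annotation, lr_table, config) {
  assert_expression_matrix(mat)
  annotation <- align_annotation(annotation, mat)
  if (expression_layer(mat) == "raw" && config$normalization != "raw") {
    mat <- normalize_counts(mat, config$normalization)
  }
  ages <- unique(annotation$age_group)
  if (length(ages) != 2) {
    stop("need exactly two age groups, got: ",
         paste(ages, collapse = ", "), call. = FALSE)
  }
  both <- tapply(annotation$age_group, annotation$subset,
                 function(a) length(unique(a)) == 2L)
  if (!all(both)) {
    warning("dropping subset(s) lacking an age group: ",
            paste(names(both)[!both], collapse = ", "), call. = FALSE)
    keep <- annotation$subset %in% names(both)[both]
    mat <- mat[, keep, drop = FALSE]
    annotation <- annotation[keep, , drop = FALSE]
  }
  have <- lr_table$ligand %in% rownames(mat) &
    lr_table$receptor %in% rownames(mat)
  skipped <- lr_table[!have, , drop = FALSE]
  if (nrow(skipped)) {
    skipped$reason <- ifelse(
      !(skipped$ligand %in% rownames(mat)) &
        !(skipped$receptor %in% rownames(mat)), "both_missing",
      ifelse(!(skipped$ligand %in% rownames(mat)),
             "ligand_missing", "receptor_missing"))
    rownames(skipped) <- NULL
  } else {
    skipped$reason <- character(0)
  }
  list(mat = mat, annotation = annotation,
       scored = lr_table[have, , drop = FALSE], skipped = skipped,
       ages = if (all(c("young", "old") %in% ages)) c("young", "old")
              else sort(ages))
}

#' Permutation p-value for one interaction
#'
#' Observed score S plus the count n of permuted scores at least as large
#' as S among `n_permutations` within-subset label shuffles; p = n/N.
#'
#' @inheritParams interaction_score
#' @param n_permutations Number of permutations N.
#' @param seed Integer seed for the shuffles.
#' @return A list with `S`, `n`, `N`, `p`.
#' @export
permutation_pvalue <- function(mat, annotation, ligand, receptor,
                               sender, receiver, age_group,
                               n_permutations = 1000, seed = 1L) {
  stopifnot(n_permutations >= 1)
  assert_expression_matrix(mat)
  annotation <- align_annotation(annotation, mat)
  genes <- unique(c(ligand, receptor))
  if (!all(genes %in% rownames(mat))) {
    stop("gene(s) not in matrix: ",
         paste(setdiff(genes, rownames(mat)), collapse = ", "),
         call. = FALSE)
  }
  subsets <- unique(annotation$subset)
  ages <- unique(annotation$age_group)
  lr <- data.frame(ligand = ligand, receptor = receptor,
                   stringsAsFactors = FALSE)
  rec <- crosstalk_records(lr, genes, subsets, ages)
  rec <- rec[rec$sender == sender & rec$receiver == receiver &
               rec$age_group == age_group, , drop = FALSE]
  if (nrow(rec) != 1L) {
    stop("unknown sender/receiver subset or age group", call. = FALSE)
  }
  E <- as.matrix(mat[genes, , drop = FALSE])
  res <- crosstalk_engine(E, annotation$subset, annotation$age_group,
                          subsets, ages, rec, n_permutations, seed)
  list(S = res$S, n = res$n, N = res$N, p = res$n / res$N)
}

#' Score and test every ligand-receptor interaction
#'
#' For every ligand-receptor pair with both genes present, every ordered
#' (sender, receiver) subset pair and each age group, computes the
#' interaction score and its within-subset age-label permutation p-value
#' (the same N sampled shuffles are shared across all records of the run).
#' An interaction is flagged significantly up-regulated in its age group
#' when p <= `alpha_crosstalk`.
#'
#' @param mat Expression matrix; a raw-layer matrix is normalized to
#'   `config$normalization` first.
#' @param annotation Cell annotation with two age groups.
#' @param lr_table Ligand-receptor pair table (see [read_lr_table()]).
#' @param config An [analysis_config()]; `n_permutations`, `seed`,
#'   `alpha_crosstalk`, `normalization` and `report_pseudo_p` apply.
#' @return A list of class `crosstalk_result`: `interactions`, a
#'   data.frame with one row per (pair, sender, receiver, age_group)
#'   carrying `S`, `n`, `N`, `p`, `significant`; and `skipped_pairs`,
#'   pairs not scored because a gene is absent, with a reason.
#' @export
run_crosstalk <- function(mat, annotation, lr_table,
                          config = analysis_config()) {
  inp <- prepare_crosstalk_input(mat, annotation, lr_table, config)
  empty <- data.frame(
    ligand = character(), receptor = character(), sender = character(),
    receiver = character(), age_group = character(), S = numeric(),
    n = integer(), N = integer(), p = numeric(), significant = logical(),
    stringsAsFactors = FALSE
  )
  if (!nrow(inp$scored) || !nrow(inp$annotation)) {
    warning("no ligand-receptor pair scoreable", call. = FALSE)
    return(structure(list(interactions = empty,
                          skipped_pairs = inp$skipped),
                     class = "crosstalk_result"))
  }
  subsets <- unique(inp$annotation$subset)
  genes <- unique(c(inp$scored$ligand, inp$scored$receptor))
  rec <- crosstalk_records(inp$scored, genes, subsets, inp$ages)
  E <- as.matrix(inp$mat[genes, , drop = FALSE])
  res <- crosstalk_engine(E, inp$annotation$subset,
                          inp$annotation$age_group, subsets, inp$ages, rec,
                          config$n_permutations, config$seed)
  interactions <- data.frame(
    ligand = rec$ligand, receptor = rec$receptor, sender = rec$sender,
    receiver = rec$receiver, age_group = rec$age_group,
    S = res$S, n = res$n, N = res$N, p = res$n / res$N,
    stringsAsFactors = FALSE
  )
  interactions$significant <- interactions$p <= config$alpha_crosstalk
  if (config$report_pseudo_p) {
    interactions$p_pseudo <- (res$n + 1) / (res$N + 1)
  }
  structure(list(interactions = interactions,
                 skipped_pairs = inp$skipped),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("Crosstalk result: %d interaction(s), %d significant; %d pair(s) skipped\n",
              nrow(x$interactions), sum(x$interactions$significant),
              nrow(x$skipped_pairs)))
  invisible(x)
}

#' Exact permutation p-values by exhaustive enumeration
#'
#' For tiny instances, enumerates every distinct joint assignment of the
#' within-subset age-label multisets and returns the exact probability
#' that a permuted score is at least as large as the observed one. Useful
#' as a ground truth for the Monte-Carlo p-values of [run_crosstalk()].
#'
#' @inheritParams run_crosstalk
#' @param max_arrangements Guard on the number of joint label
#'   arrangements enumerated.
#' @return As the `interactions` element of [run_crosstalk()], with
#'   columns `S`, `p_exact`, and `n_arrangements`.
#' @export
exact_crosstalk_pvalues <- function(mat, annotation, lr_table,
                                    config = analysis_config(),
                                    max_arrangements = 1e5) {
  inp <- prepare_crosstalk_input(mat, annotation, lr_table, config)
  if (!nrow(inp$scored)) stop("no ligand-receptor pair scoreable",
                              call. = FALSE)
  annotation <- inp$annotation
  subsets <- unique(annotation$subset)
  ages <- inp$ages
  genes <- unique(c(inp$scored$ligand, inp$scored$receptor))
  rec <- crosstalk_records(inp$scored, genes, subsets, ages)
  E <- as.matrix(inp$mat[genes, , drop = FALSE])
  tE <- t(E)
  n_groups <- length(subsets) * length(ages)

  # per subset: all distinct positions of the first age label
  per_subset <- lapply(subsets, function(s) {
    idx <- which(annotation$subset == s)
    k <- sum(annotation$age_group[idx] == ages[[1]])
    list(idx = idx, sets = utils::combn(length(idx), k, simplify = FALSE))
  })
  n_arr <- prod(vapply(per_subset, function(x) length(x$sets), numeric(1)))
  if (n_arr > max_arrangements) {
    stop("instance has ", n_arr, " label arrangements; enumeration capped at ",
         max_arrangements, call. = FALSE)
  }

  gid0 <- match(annotation$subset, subsets) +
    length(subsets) * (match(annotation$age_group, ages) - 1L)
  M0 <- group_mean_table(tE, gid0, n_groups, tabulate(gid0, n_groups))
  S <- M0[cbind(rec$cs, rec$li)] * M0[cbind(rec$cr, rec$ri)]

  counts <- integer(nrow(rec))
  choice <- rep(1L, length(per_subset))
  n_sets <- vapply(per_subset, function(x) length(x$sets), integer(1))
  for (a in seq_len(n_arr)) {
    perm_age <- character(nrow(annotation))
    for (s in seq_along(per_subset)) {
      idx <- per_subset[[s]]$idx
      first <- per_subset[[s]]$sets[[choice[[s]]]]
      perm_age[idx] <- ages[[2]]
      perm_age[idx[first]] <- ages[[1]]
    }
    gid <- match(annotation$subset, subsets) +
      length(subsets) * (match(perm_age, ages) - 1L)
    Mp <- group_mean_table(tE, gid, n_groups, tabulate(gid, n_groups))
    Sp <- Mp[cbind(rec$cs, rec$li)] * Mp[cbind(rec$cr, rec$ri)]
    counts <- counts + (Sp >= S)
    # odometer over the per-subset choice vector
    for (s in seq_along(choice)) {
      choice[[s]] <- choice[[s]] + 1L
      if (choice[[s]] <= n_sets[[s]]) break
      choice[[s]] <- 1L
    }
  }
  data.frame(
    ligand = rec$ligand, receptor = rec$receptor, sender = rec$sender,
    receiver = rec$receiver, age_group = rec$age_group, S = S,
    p_exact = counts / n_arr, n_arrangements = n_arr,
    stringsAsFactors = FALSE
  )
}

#' Write crosstalk results
#'
#' `interactions.tsv` (one row per scored interaction) and
#' `skipped_pairs.tsv` under `dir`, each with an audit header.
#'
#' @param result A `crosstalk_result`.
#' @param dir Output directory.
#' @param config The `analysis_config` of the run, recorded in headers.
#' @export
write_crosstalk_result <- function(result, dir,
                                   config = analysis_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_result_table(result$interactions,
                     file.path(dir, "interactions.tsv"), config)
  write_result_table(result$skipped_pairs,
                     file.path(dir, "skipped_pairs.tsv"), config)
  invisible(dir)
}
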