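#' Configuration for the synthetic single-cell generator
#'
#' Describes a two-age-group, multi-subset single-cell experiment with
#' negative-binomial (gamma-Poisson) counts, log-normal library-size
#' variation, a block of mitochondrial genes, optional planted low-quality
#' cells, and optional planted age-specific shifts in ligand/receptor means.
#'
#' Gene names are deterministic: mitochondrial genes first (named with
#' `mito_prefix`, e.g. `MT-ND1`), then every gene named in
#' `planted_effects`, then filler genes `GENE0001`, `GENE0002`, ... up to
#' `n_genes`. Subset names default to `MSC`, `adipocyte1`, `adipocyte2`,
#' `fibroblast`, `endothelial`, then `subset6`, ...
#'
#' @param n_subsets Number of cell subsets.
#' @param cells_per_subset_per_age Cells per (subset, age group) block.
#' @param n_genes Total genes, mitochondrial included.
#' @param n_mito_genes Mitochondrial genes (<= `n_genes`).
#' @param baseline_mean Expected counts per gene per cell for a cell of
#'   average library size.
#' @param dispersion Negative-binomial size parameter; variance is
#'   `mu + mu^2 / dispersion`.
#' @param planted_effects Data.frame with columns `ligand`, `receptor`,
#'   `sender_subset`, `receiver_subset`, `age_group`, `fold` (see
#'   [planted_effect()]); the ligand mean in (sender, age) cells and the
#'   receptor mean in (receiver, age) cells are multiplied by `fold`.
#' @param n_lowquality_cells Extra cells planted to fail quality control,
#'   by detected-gene downsampling, mitochondrial boosting, or both
#'   (cycled in that order).
#' @param lowquality_gene_fraction Fraction of genes a downsampled
#'   low-quality cell still expresses.
#' @param lowquality_mito_share Expected mitochondrial count share of a
#'   mito-boosted low-quality cell.
#' @param n_decoy_pairs Ligand-receptor decoy pairs drawn from filler genes
#'   carrying no planted effect.
#' @param libsize_sdlog Log-normal sd of per-cell library-size factors
#'   (mean factor is 1; 0 disables the variation).
#' @param mito_prefix Name prefix for mitochondrial genes.
#' @param mito_mean_factor Mean multiplier for mitochondrial genes relative
#'   to `baseline_mean`.
#' @param seed Integer seed; a fixed config yields byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subsets = 3,
                       cells_per_subset_per_age = 200,
                       n_genes = 500,
                       n_mito_genes = 13,
                       baseline_mean = 2,
                       dispersion = 2,
                       planted_effects = NULL,
                       n_lowquality_cells = 0,
                       lowquality_gene_fraction = 0.2,
                       lowquality_mito_share = 0.3,
                       n_decoy_pairs = 30,
                       libsize_sdlog = 0.25,
                       mito_prefix = "MT-",
                       mito_mean_factor = 2,
                       seed = 1L) {
  if (is.null(planted_effects)) {
    planted_effects <- planted_effect()[0, ]
  }
  stopifnot(
    n_subsets >= 1, cells_per_subset_per_age >= 1,
    n_genes >= 1, n_mito_genes >= 0, n_mito_genes <= n_genes,
    baseline_mean > 0, dispersion > 0,
    n_lowquality_cells >= 0,
    lowquality_gene_fraction > 0, lowquality_gene_fraction < 1,
    lowquality_mito_share > 0, lowquality_mito_share < 1,
    n_decoy_pairs >= 0, libsize_sdlog >= 0, mito_mean_factor > 0,
    is.data.frame(planted_effects),
    all(planted_effects$fold > 0)
  )
  structure(list(
    n_subsets = as.integer(n_subsets),
    cells_per_subset_per_age = as.integer(cells_per_subset_per_age),
    n_genes = as.integer(n_genes),
    n_mito_genes = as.integer(n_mito_genes),
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    planted_effects = planted_effects,
    n_lowquality_cells = as.integer(n_lowquality_cells),
    lowquality_gene_fraction = lowquality_gene_fraction,
    lowquality_mito_share = lowquality_mito_share,
    n_decoy_pairs = as.integer(n_decoy_pairs),
    libsize_sdlog = libsize_sdlog,
    mito_prefix = mito_prefix,
    mito_mean_factor = mito_mean_factor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Describe a planted ligand-receptor effect
#'
#' @param ligand,receptor Gene names; added to the simulated gene panel.
#' @param sender_subset,receiver_subset Subset names; must exist in the
#'   simulated dataset.
#' @param age_group Age group (`"young"` or `"old"`) whose cells carry the
#'   shifted means.
#' @param fold Positive multiplier applied to the ligand mean in the sender
#'   block and the receptor mean in the receiver block.
#' @return One-row data.frame; `rbind` several to plant several effects.
#' @export
planted_effect <- function(ligand = character(), receptor = character(),
                           sender_subset = character(),
                           receiver_subset = character(),
                           age_group = character(), fold = numeric()) {
  data.frame(ligand = ligand, receptor = receptor,
             sender_subset = sender_subset,
             receiver_subset = receiver_subset,
             age_group = age_group, fold = fold,
             stringsAsFactors = FALSE)
}

default_subset_names <- function(n) {
  pool <- c("MSC", "adipocyte1", "adipocyte2", "fibroblast", "endothelial")
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0("subset", seq(length(pool) + 1L, n)))
}

mito_gene_names <- function(n, prefix) {
  core <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
            "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB")
  if (n > length(core)) core <- c(core, paste0("G", seq(length(core) + 1L, n)))
  paste0(prefix, core[seq_len(n)])
}

#' Generate a synthetic single-cell dataset with known ground truth
#'
#' Draws a genes x cells negative-binomial count matrix for `n_subsets`
#' cell subsets in two age groups, applies the planted ligand/receptor
#' mean shifts, plants low-quality cells, and assembles a ligand-receptor
#' table mixing the planted pairs with effect-free decoy pairs.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (sparse counts, raw layer),
#'   `annotation` (cell_id, subset, age_group), `lr_table` (ligand,
#'   receptor, source in {planted, decoy}), and `truth` (list with
#'   `effects`, the planted-effect table, and `lowquality_cells`, the ids
#'   of cells planted to fail QC).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  effects <- config$planted_effects
  subsets <- default_subset_names(config$n_subsets)
  bad_subset <- setdiff(c(effects$sender_subset, effects$receiver_subset),
                        subsets)
  if (length(bad_subset)) {
    stop("planted effect names unknown subset(s): ",
         paste(unique(bad_subset), collapse = ", "), call. = FALSE)
  }

  mito_genes <- mito_gene_names(config$n_mito_genes, config$mito_prefix)
  effect_genes <- unique(c(effects$ligand, effects$receptor))
  if (any(effect_genes %in% mito_genes)) {
    stop("planted effects may not target mitochondrial genes", call. = FALSE)
  }
  n_named <- config$n_mito_genes + length(effect_genes)
  if (n_named > config$n_genes) {
    stop("n_genes too small for the mitochondrial and planted genes (need >= ",
         n_named, ")", call. = FALSE)
  }
  filler <- sprintf("GENE%04d", seq_len(config$n_genes - n_named))
  genes <- c(mito_genes, effect_genes, filler)

  with_rng_seed(config$seed, {
    out <- simulate_counts(config, genes, mito_genes, subsets, effects)
    lr_table <- build_lr_table(effects, filler, config$n_decoy_pairs)
    list(
      matrix = out$matrix,
      annotation = out$annotation,
      lr_table = lr_table,
      truth = list(effects = effects, lowquality_cells = out$lowquality_cells)
    )
  })
}

#' Generate a null dataset with exchangeable age labels
#'
#' Identical generative law for young and old cells (no planted effects
#' allowed), so age labels carry no expression information and the
#' crosstalk permutation test should be calibrated on the output.
#'
#' @param config A [sim_config()] with empty `planted_effects`.
#' @return A list with `matrix`, `annotation`, `lr_table`.
#' @export
make_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$planted_effects) > 0) {
    stop("a null dataset cannot carry planted effects", call. = FALSE)
  }
  generate_dataset(config)[c("matrix", "annotation", "lr_table")]
}

# Count sampling: per-cell expected values are
#   baseline_mean * mito_factor(gene) * libsize(cell) * planted fold,
# drawn NB with the configured size. Low-quality corruption edits the mean
# matrix before sampling so QC outcomes hold by construction.
simulate_counts <- function(config, genes, mito_genes, subsets, effects) {
  blocks <- expand.grid(age_group = c("young", "old"), subset = subsets,
                        stringsAsFactors = FALSE)[, 2:1]
  annotation <- data.frame(
    subset = rep(blocks$subset, each = config$cells_per_subset_per_age),
    age_group = rep(blocks$age_group, each = config$cells_per_subset_per_age),
    stringsAsFactors = FALSE
  )
  lq_reasons <- character(0)
  if (config$n_lowquality_cells > 0) {
    idx <- seq_len(config$n_lowquality_cells)
    lq <- data.frame(
      subset = subsets[(idx - 1L) %% length(subsets) + 1L],
      age_group = c("young", "old")[(idx - 1L) %% 2L + 1L],
      stringsAsFactors = FALSE
    )
    annotation <- rbind(annotation, lq)
    lq_reasons <- c("low_genes", "high_mito", "both")[(idx - 1L) %% 3L + 1L]
  }
  n_cells <- nrow(annotation)
  annotation <- cbind(cell_id = sprintf("cell%05d", seq_len(n_cells)),
                      annotation)
  lq_cells <- utils::tail(annotation$cell_id, config$n_lowquality_cells)

  gene_means <- rep(config$baseline_mean, length(genes))
  names(gene_means) <- genes
  gene_means[mito_genes] <- config$baseline_mean * config$mito_mean_factor
  sf <- if (config$libsize_sdlog > 0) {
    rlnorm(n_cells, meanlog = -config$libsize_sdlog^2 / 2,
           sdlog = config$libsize_sdlog)
  } else rep(1, n_cells)

  mu <- outer(gene_means, sf)
  dimnames(mu) <- list(genes, annotation$cell_id)

  for (k in seq_len(nrow(effects))) {
    e <- effects[k, ]
    send <- annotation$subset == e$sender_subset &
      annotation$age_group == e$age_group
    recv <- annotation$subset == e$receiver_subset &
      annotation$age_group == e$age_group
    mu[e$ligand, send] <- mu[e$ligand, send] * e$fold
    mu[e$receptor, recv] <- mu[e$receptor, recv] * e$fold
  }

  is_mito <- genes %in% mito_genes
  for (k in seq_along(lq_cells)) {
    cell <- lq_cells[[k]]
    reason <- lq_reasons[[k]]
    if (reason %in% c("low_genes", "both")) {
      nonmito <- which(!is_mito)
      n_keep <- max(1L, floor(config$lowquality_gene_fraction *
                                length(nonmito)))
      drop <- setdiff(nonmito, sample(nonmito, n_keep))
      mu[drop, cell] <- 0
      # scale mito means too so the mito share stays at baseline
      mu[is_mito, cell] <- mu[is_mito, cell] * n_keep / length(nonmito)
    }
    if (reason %in% c("high_mito", "both")) {
      s <- config$lowquality_mito_share
      mito_total <- sum(mu[is_mito, cell])
      other_total <- sum(mu[!is_mito, cell])
      if (mito_total > 0) {
        mu[is_mito, cell] <- mu[is_mito, cell] *
          (s / (1 - s)) * other_total / mito_total
      }
    }
  }

  counts <- matrix(
    rnbinom(length(mu), size = config$dispersion, mu = as.vector(mu)),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  expression_layer(counts) <- "raw"
  list(matrix = counts, annotation = annotation, lowquality_cells = lq_cells)
}

# Planted pairs plus decoys drawn (without replacement) from filler genes
# carrying no effect; ligand and receptor of a decoy are distinct genes.
build_lr_table <- function(effects, filler, n_decoy_pairs) {
  planted <- if (nrow(effects)) {
    unique(data.frame(ligand = effects$ligand, receptor = effects$receptor,
                      source = "planted", stringsAsFactors = FALSE))
  } else {
    data.frame(ligand = character(), receptor = character(),
               source = character(), stringsAsFactors = FALSE)
  }
  if (n_decoy_pairs > 0) {
    if (length(filler) < 2 * n_decoy_pairs) {
      stop("not enough effect-free genes for ", n_decoy_pairs,
           " decoy pairs", call. = FALSE)
    }
    picks <- matrix(sample(filler, 2 * n_decoy_pairs), ncol = 2)
    planted <- rbind(planted, data.frame(
      ligand = picks[, 1], receptor = picks[, 2], source = "decoy",
      stringsAsFactors = FALSE
    ))
  }
  rownames(planted) <- NULL
  planted
}

#' Write a generated dataset to a directory
#'
#' Writes the MatrixMarket triplet plus `annotation.tsv`, `lr_pairs.tsv`
#' and, when present, `truth_effects.tsv` / `truth_lowquality_cells.tsv`.
#'
#' @param dataset Output of [generate_dataset()] or [make_null_dataset()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(dataset$matrix, dir)
  write_annotation(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_lr_table(dataset$lr_table, file.path(dir, "lr_pairs.tsv"))
  if (!is.null(dataset$truth)) {
    write.table(dataset$truth$effects, file.path(dir, "truth_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(dataset$truth$lowquality_cells,
               file.path(dir, "truth_lowquality_cells.tsv"))
  }
  invisible(dir)
}
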