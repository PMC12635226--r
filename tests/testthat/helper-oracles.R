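# Fixture builders and independent oracles used across the suite.

# genes x cells base matrix with deterministic names
named_matrix <- function(values, n_genes, n_cells,
                         genes = sprintf("g%02d", seq_len(n_genes)),
                         cells = sprintf("c%02d", seq_len(n_cells))) {
  matrix(values, nrow = n_genes, ncol = n_cells,
         dimnames = list(genes, cells))
}

toy_annotation <- function(cells, subsets, ages) {
  data.frame(cell_id = cells, subset = subsets, age_group = ages,
             stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value by full enumeration of group labelings.
# Independent of stats::wilcox.test: enumerates every way to pick which
# pooled observations belong to group a and compares rank sums to the
# observed one through the symmetric two-sided rule.
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  k <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(k)])
  mu <- k * (n + 1) / 2
  sets <- utils::combn(n, k)
  stats <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Manual Benjamini-Hochberg step-up, written from the definition.
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force exact crosstalk p-values for tiny instances: enumerates all
# within-subset age-label arrangements with nested loops and recomputes
# every group mean by explicit masking. Deliberately naive and slow.
naive_exact_crosstalk <- function(mat, annotation, lr_table, age_groups) {
  subsets <- unique(annotation$subset)
  arrangements_for <- function(s) {
    idx <- which(annotation$subset == s)
    labs <- annotation$age_group[idx]
    first <- age_groups[[1]]
    sets <- utils::combn(length(idx), sum(labs == first), simplify = FALSE)
    lapply(sets, function(pos) {
      out <- rep(age_groups[[2]], length(idx))
      out[pos] <- first
      out
    })
  }
  per_subset <- lapply(subsets, arrangements_for)
  grid <- expand.grid(lapply(per_subset, seq_along))

  masked_mean <- function(ann_age, subset, age, gene) {
    cells <- annotation$subset == subset & ann_age == age
    mean(mat[gene, cells])
  }
  score <- function(ann_age, lig, rec, se, rc, ag) {
    masked_mean(ann_age, se, ag, lig) * masked_mean(ann_age, rc, ag, rec)
  }

  out <- expand.grid(pair = seq_len(nrow(lr_table)), sender = subsets,
                     receiver = subsets, age_group = age_groups,
                     stringsAsFactors = FALSE)
  out$ligand <- lr_table$ligand[out$pair]
  out$receptor <- lr_table$receptor[out$pair]
  out$p_exact <- NA_real_
  for (i in seq_len(nrow(out))) {
    S <- score(annotation$age_group, out$ligand[i], out$receptor[i],
               out$sender[i], out$receiver[i], out$age_group[i])
    hits <- 0L
    for (g in seq_len(nrow(grid))) {
      ann_age <- annotation$age_group
      for (s in seq_along(subsets)) {
        idx <- which(annotation$subset == subsets[[s]])
        ann_age[idx] <- per_subset[[s]][[grid[g, s]]]
      }
      Sp <- score(ann_age, out$ligand[i], out$receptor[i],
                  out$sender[i], out$receiver[i], out$age_group[i])
      if (Sp >= S) hits <- hits + 1L
    }
    out$p_exact[i] <- hits / nrow(grid)
  }
  out
}

# Deterministic QC fixture: 250 genes (10 mitochondrial) x 7 cells where
# every filter outcome is forced by construction.
#   keep1: exactly 200 detected genes, exactly 10% mito -> kept (boundaries)
#   low1:  199 detected, low mito                       -> removed, low_genes
#   mito1: 220 detected, 22% mito                       -> removed, high_mito
#   both1: 160 detected, 40% mito                       -> removed, both
#   h1-h3: healthy                                      -> kept
# After cell filtering, gene r240 sits in 2 surviving cells (removed) and
# r239 in exactly 3 (kept, strict inequality).
qc_toy <- function() {
  genes <- c(sprintf("MT-%02d", 1:10), sprintf("r%03d", 1:240))
  cells <- c("keep1", "low1", "mito1", "both1", "h1", "h2", "h3")
  m <- matrix(0, length(genes), length(cells),
              dimnames = list(genes, cells))
  mito <- 1:10
  reg <- function(i) 10 + i
  # keep1: 190 regular (110 x1, 80 x2 = 270 counts) + 10 mito x3 (30)
  m[reg(1:110), "keep1"] <- 1
  m[reg(111:190), "keep1"] <- 2
  m[mito, "keep1"] <- 3
  # low1: 195 regular x1 + 4 mito x1 -> 199 detected, 4/199 mito
  m[reg(1:195), "low1"] <- 1
  m[mito[1:4], "low1"] <- 1
  # mito1: 210 regular x1 + 10 mito x6 -> 220 detected, 60/270 mito
  m[reg(1:210), "mito1"] <- 1
  m[mito, "mito1"] <- 6
  # both1: 150 regular x1 + 10 mito x10 -> 160 detected, 100/250 mito
  m[reg(1:150), "both1"] <- 1
  m[mito, "both1"] <- 10
  # healthy: everything x1 except r240 in h3; mito x2
  for (h in c("h1", "h2", "h3")) {
    m[, h] <- 1
    m[mito, h] <- 2
  }
  m["r240", "h3"] <- 0
  m
}

qc_toy_annotation <- function(m) {
  toy_annotation(colnames(m), rep("MSC", ncol(m)),
                 rep(c("young", "old"), length.out = ncol(m)))
}

# Small simulated dataset shared by several tests.
small_planted_dataset <- function(fold = 4, seed = 101,
                                  cells = 200, subsets = 2) {
  cfg <- sim_config(
    n_subsets = subsets, cells_per_subset_per_age = cells,
    n_genes = 300, n_mito_genes = 8,
    planted_effects = planted_effect("PLAU", "PLAUR", "MSC", "MSC",
                                     "old", fold),
    n_decoy_pairs = 20, seed = seed
  )
  generate_dataset(cfg)
}
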