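test_that("empty planted effects give empty truth and seeded runs are identical", {
  cfg <- sim_config(n_subsets = 2, cells_per_subset_per_age = 20,
                    n_genes = 60, n_mito_genes = 4, n_decoy_pairs = 5,
                    seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(nrow(d1$truth$effects), 0)
  expect_identical(as.matrix(d1$matrix), as.matrix(d2$matrix))
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$lr_table, d2$lr_table)

  d3 <- generate_dataset(sim_config(n_subsets = 2,
                                    cells_per_subset_per_age = 20,
                                    n_genes = 60, n_mito_genes = 4,
                                    n_decoy_pairs = 5, seed = 43))
  expect_false(identical(as.matrix(d1$matrix), as.matrix(d3$matrix)))
})

test_that("null dataset has the arithmetic cell count and rejects planted effects", {
  cfg <- sim_config(n_subsets = 2, cells_per_subset_per_age = 100,
                    n_genes = 50, n_mito_genes = 2, n_decoy_pairs = 3,
                    seed = 1)
  d <- make_null_dataset(cfg)
  expect_equal(nrow(d$annotation), 400)
  expect_equal(ncol(d$matrix), 400)
  expect_null(d$truth)

  cfg2 <- sim_config(planted_effects = planted_effect(
    "PLAU", "PLAUR", "MSC", "MSC", "old", 2), seed = 1)
  expect_error(make_null_dataset(cfg2), "planted")
})

test_that("counts match the configured negative-binomial moments", {
  # 6000 iid draws at mean 2, size 5; no library-size variation
  cfg <- sim_config(n_subsets = 1, cells_per_subset_per_age = 60,
                    n_genes = 50, n_mito_genes = 0, baseline_mean = 2,
                    dispersion = 5, libsize_sdlog = 0, n_decoy_pairs = 0,
                    seed = 77)
  d <- make_null_dataset(cfg)
  draws <- as.vector(as.matrix(d$matrix))
  se <- sqrt((2 + 2^2 / 5) / length(draws))
  expect_lt(abs(mean(draws) - 2), 3 * se)
  expect_true(all(draws >= 0))
  expect_true(all(draws == round(draws)))
})

test_that("a planted fold is realized in the ligand and receptor means", {
  d <- small_planted_dataset(fold = 3, seed = 55)
  ann <- d$annotation
  lig_old <- group_mean(d$matrix, ann, "MSC", "old", "PLAU")
  lig_young <- group_mean(d$matrix, ann, "MSC", "young", "PLAU")
  rec_old <- group_mean(d$matrix, ann, "MSC", "old", "PLAUR")
  rec_young <- group_mean(d$matrix, ann, "MSC", "young", "PLAUR")
  expect_lt(abs(lig_old / lig_young - 3), 0.2 * 3)
  expect_lt(abs(rec_old / rec_young - 3), 0.2 * 3)
  # untouched subset is unshifted
  other_old <- group_mean(d$matrix, ann, "adipocyte1", "old", "PLAU")
  other_young <- group_mean(d$matrix, ann, "adipocyte1", "young", "PLAU")
  expect_lt(abs(other_old / other_young - 1), 0.25)
})

test_that("planted effects naming unknown subsets or clashing genes error", {
  expect_error(generate_dataset(sim_config(
    n_subsets = 2,
    planted_effects = planted_effect("A", "B", "nosuch", "MSC", "old", 2)
  )), "unknown subset")
  expect_error(sim_config(planted_effects = planted_effect(
    "A", "B", "MSC", "MSC", "old", -1)))
  expect_error(generate_dataset(sim_config(
    n_genes = 10, n_mito_genes = 9,
    planted_effects = planted_effect("A", "B", "MSC", "MSC", "old", 2)
  )), "n_genes too small")
})

test_that("planted low-quality cells fail the QC thresholds by construction", {
  cfg <- sim_config(n_subsets = 2, cells_per_subset_per_age = 50,
                    n_lowquality_cells = 9, n_decoy_pairs = 0, seed = 9)
  d <- generate_dataset(cfg)
  lq <- d$truth$lowquality_cells
  expect_length(lq, 9)
  detected <- detect_genes_per_cell(d$matrix)
  mfrac <- mito_fraction(d$matrix)
  fails <- detected[lq] < 200 | mfrac[lq] > 0.10
  expect_true(all(fails))
  # regular cells overwhelmingly pass
  regular <- setdiff(colnames(d$matrix), lq)
  pass <- detected[regular] >= 200 & mfrac[regular] <= 0.10
  expect_gt(mean(pass), 0.95)
})

test_that("decoy pairs carry no age signal (uniform Wilcoxon p-values)", {
  cfg <- sim_config(n_subsets = 1, cells_per_subset_per_age = 100,
                    n_genes = 450, n_mito_genes = 5, n_decoy_pairs = 200,
                    seed = 31)
  d <- make_null_dataset(cfg)
  ann <- d$annotation
  old <- ann$cell_id[ann$age_group == "old"]
  young <- ann$cell_id[ann$age_group == "young"]
  decoys <- d$lr_table[d$lr_table$source == "decoy", ]
  expect_gte(nrow(decoys), 200)
  pvals <- vapply(decoys$ligand, function(g) {
    wilcoxon_test(as.numeric(d$matrix[g, old]),
                  as.numeric(d$matrix[g, young]))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("datasets round-trip through the on-disk layout byte-identically", {
  cfg <- sim_config(n_subsets = 2, cells_per_subset_per_age = 15,
                    n_genes = 40, n_mito_genes = 3, n_decoy_pairs = 4,
                    planted_effects = planted_effect("L1", "R1", "MSC",
                                                     "adipocyte1", "old", 2),
                    seed = 5)
  d <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  mat <- read_matrix(file.path(dir, "matrix.mtx"),
                     file.path(dir, "features.tsv"),
                     file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(mat), as.matrix(d$matrix))
  expect_equal(read_annotation(file.path(dir, "annotation.tsv")),
               d$annotation, ignore_attr = TRUE)
  expect_equal(read_lr_table(file.path(dir, "lr_pairs.tsv")),
               d$lr_table, ignore_attr = TRUE)
})
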