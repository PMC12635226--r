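test_that("group means and interaction scores follow their definitions", {
  mat <- named_matrix(0, 2, 5, genes = c("L", "R"))
  mat["L", ] <- c(1, 3, 0, 0, 0)
  mat["R", ] <- c(0, 0, 2, 2, 5)
  ann <- toy_annotation(colnames(mat),
                        c("A", "A", "B", "B", "B"),
                        c("old", "old", "old", "old", "old"))
  expect_equal(group_mean(mat, ann, "A", "old", "L"), 2)
  expect_equal(group_mean(mat, ann, "B", "old", "R"), 3)
  expect_equal(interaction_score(mat, ann, "L", "R", "A", "B", "old"), 6)
  # zero ligand mean annihilates the score
  expect_equal(interaction_score(mat, ann, "R", "R", "A", "B", "old"), 0)
  expect_error(group_mean(mat, ann, "A", "young", "L"), "no cells")
  expect_error(group_mean(mat, ann, "A", "old", "nope"), "not in matrix")

  set.seed(3)
  big <- named_matrix(rpois(500, 4), 10, 50)
  ann2 <- toy_annotation(colnames(big), rep(c("A", "B"), 25),
                         rep(c("young", "old"), each = 25))
  cells <- ann2$subset == "A" & ann2$age_group == "old"
  expect_equal(group_mean(big, ann2, "A", "old", "g03"),
               mean(as.matrix(big)["g03", cells]))
})

test_that("age labels are shuffled within subsets, uniformly and reproducibly", {
  ann <- toy_annotation(sprintf("c%d", 1:8),
                        rep(c("s1", "s2"), each = 4),
                        rep(c("old", "old", "young", "young"), 2))
  perm <- permute_age_labels(ann, seed = 4)
  expect_equal(perm$subset, ann$subset)
  for (s in c("s1", "s2")) {
    expect_equal(sort(perm$age_group[perm$subset == s]),
                 sort(ann$age_group[ann$subset == s]))
  }
  expect_identical(permute_age_labels(ann, seed = 4), perm)

  # all C(4,2) = 6 arrangements of one subset appear uniformly
  draws <- withr::with_seed(99, {
    replicate(6000, paste(permute_age_labels(ann)$age_group[1:4],
                          collapse = ""))
  })
  tab <- table(draws)
  expect_length(tab, 6)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  single <- toy_annotation(c("a", "b"), c("s1", "s1"), c("old", "old"))
  expect_warning(permute_age_labels(single), "single age group")
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration on a toy instance", {
  cfg <- sim_config(n_subsets = 2, cells_per_subset_per_age = 2,
                    n_genes = 20, n_mito_genes = 2, n_decoy_pairs = 4,
                    planted_effects = planted_effect("L1", "R1", "MSC",
                                                     "adipocyte1", "old", 5),
                    seed = 23)
  d <- generate_dataset(cfg)
  ac <- analysis_config(n_permutations = 4000, seed = 7,
                        normalization = "raw")
  exact <- exact_crosstalk_pvalues(d$matrix, d$annotation, d$lr_table, ac)
  expect_equal(unique(exact$n_arrangements), 36)
  mc <- run_crosstalk(d$matrix, d$annotation, d$lr_table, ac)$interactions
  key <- function(x) paste(x$ligand, x$receptor, x$sender, x$receiver,
                           x$age_group)
  exact <- exact[match(key(mc), key(exact)), ]
  expect_equal(mc$S, exact$S)
  expect_lt(max(abs(mc$p - exact$p_exact)), 0.03)

  # the exported enumeration agrees with a naive masked-mean oracle
  naive <- naive_exact_crosstalk(as.matrix(d$matrix), d$annotation,
                                 d$lr_table[1:3, ], c("young", "old"))
  exact3 <- exact_crosstalk_pvalues(d$matrix, d$annotation,
                                    d$lr_table[1:3, ], ac)
  naive <- naive[match(key(exact3), key(naive)), ]
  expect_equal(exact3$p_exact, naive$p_exact)
})

test_that("hand-enumerated two-cell instance gives the frozen exact p-values", {
  # one subset, one young cell (L=1, R=1) and one old cell (L=3, R=2):
  # arrangements = identity and swap; S_old = 6 vs {6, 1} -> p = 1/2;
  # S_young = 1 vs {1, 6} -> p = 1
  mat <- named_matrix(c(1, 1, 3, 2), 2, 2, genes = c("L", "R"))
  ann <- toy_annotation(colnames(mat), c("s", "s"), c("young", "old"))
  lr <- data.frame(ligand = "L", receptor = "R", source = "x")
  exact <- exact_crosstalk_pvalues(mat, ann, lr,
                                   analysis_config(normalization = "raw"))
  expect_equal(exact$p_exact[exact$age_group == "old"], 0.5)
  expect_equal(exact$p_exact[exact$age_group == "young"], 1)
})

test_that("p arithmetic is exact and the constant matrix degenerates to p = 1", {
  d <- small_planted_dataset(fold = 2, seed = 3, cells = 20)
  ac <- analysis_config(n_permutations = 1000, seed = 5)
  res <- run_crosstalk(d$matrix, d$annotation, d$lr_table, ac)$interactions
  expect_true(all(res$p * res$N == res$n))
  expect_true(all(res$n >= 0 & res$n <= res$N))
  expect_equal(res$significant, res$p <= 0.01)

  # at N where n/N is not exactly representable, n and N stay authoritative
  ac157 <- analysis_config(n_permutations = 157, seed = 5)
  res157 <- run_crosstalk(d$matrix, d$annotation, d$lr_table,
                          ac157)$interactions
  expect_identical(res157$p, res157$n / res157$N)
  expect_true(all(round(res157$p * res157$N) == res157$n))

  const <- named_matrix(3, 2, 12, genes = c("L", "R"))
  ann <- toy_annotation(colnames(const), rep(c("A", "B"), 6),
                        rep(c("young", "old"), each = 6))
  lr <- data.frame(ligand = "L", receptor = "R", source = "x")
  res2 <- run_crosstalk(const, ann, lr,
                        analysis_config(n_permutations = 200, seed = 1,
                                        normalization = "raw"))$interactions
  expect_true(all(res2$p == 1))
  expect_true(all(res2$S == 9))
})

test_that("runs are deterministic and scale-covariant", {
  d <- small_planted_dataset(fold = 3, seed = 17, cells = 30)
  ac <- analysis_config(n_permutations = 300, seed = 11)
  r1 <- run_crosstalk(d$matrix, d$annotation, d$lr_table, ac)
  r2 <- run_crosstalk(d$matrix, d$annotation, d$lr_table, ac)
  expect_identical(r1$interactions, r2$interactions)

  # multiplying the expression layer by c scales S by c^2, p unchanged
  norm <- normalize_counts(d$matrix, "cp10k")
  ac_raw <- analysis_config(n_permutations = 300, seed = 11,
                            normalization = "raw")
  base <- run_crosstalk(norm, d$annotation, d$lr_table, ac_raw)$interactions
  scaled <- run_crosstalk(norm * 7, d$annotation, d$lr_table,
                          ac_raw)$interactions
  expect_equal(scaled$S, base$S * 49)
  expect_equal(scaled$p, base$p)
})

test_that("pairs with absent genes are skipped with a reason, not scored", {
  d <- small_planted_dataset(fold = 2, seed = 29, cells = 15)
  lr <- rbind(d$lr_table[1:2, ],
              data.frame(ligand = "GHOST", receptor = "PLAUR",
                         source = "x"),
              data.frame(ligand = "NOPE1", receptor = "NOPE2",
                         source = "x"))
  res <- run_crosstalk(d$matrix, d$annotation, lr,
                       analysis_config(n_permutations = 50, seed = 2))
  expect_equal(nrow(res$skipped_pairs), 2)
  expect_setequal(res$skipped_pairs$reason,
                  c("ligand_missing", "both_missing"))
  expect_false(any(res$interactions$ligand %in% c("GHOST", "NOPE1")))
})

test_that("a larger planted fold never raises the planted p on average", {
  mean_p <- function(fold) {
    ps <- vapply(1:20, function(i) {
      d <- small_planted_dataset(fold = fold, seed = 400 + i, cells = 25)
      ac <- analysis_config(n_permutations = 200, seed = 400 + i)
      res <- run_crosstalk(d$matrix, d$annotation, d$lr_table,
                           ac)$interactions
      res$p[res$ligand == "PLAU" & res$sender == "MSC" &
              res$receiver == "MSC" & res$age_group == "old"]
    }, numeric(1))
    mean(ps)
  }
  expect_lte(mean_p(3), mean_p(1.5))
})

test_that("the bias-corrected p-value is reported on request", {
  d <- small_planted_dataset(fold = 2, seed = 12, cells = 15)
  res <- run_crosstalk(d$matrix, d$annotation, d$lr_table,
                       analysis_config(n_permutations = 100, seed = 3,
                                       report_pseudo_p = TRUE))$interactions
  expect_true("p_pseudo" %in% names(res))
  expect_equal(res$p_pseudo, (res$n + 1) / (res$N + 1))
})
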