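lr_toy <- function() {
  # 6 cells, two types; L expressed mostly in "sender", R in "receiver"
  m <- Matrix::Matrix(matrix(c(
    2, 3, 1, 0, 0, 0,   # L
    0, 1, 0, 2, 2, 3,   # R
    1, 1, 1, 1, 1, 1    # H (housekeeping)
  ), nrow = 3, byrow = TRUE), sparse = TRUE)
  dimnames(m) <- list(c("L", "R", "H"), sprintf("c%d", 1:6))
  cells <- tibble::tibble(cell_id = colnames(m), sample_id = "s1",
                          condition = "metastatic",
                          cell_type = rep(c("sender", "receiver"), each = 3))
  db <- tibble::tibble(pair_id = "LR0001", ligand = "L", receptor = "R")
  list(m = m, cells = cells, db = db)
}

test_that("the expression-fraction screen applies the 10% rule to both ends", {
  # ligand expressed in 9% of sender cells -> excluded; at 10% -> included
  n <- 100
  lig <- c(rep(1, 9), rep(0, n - 9))
  rec <- rep(1, n)
  m <- Matrix::Matrix(rbind(L = c(lig, rep(0, n)), R = c(rep(0, n), rec)), sparse = TRUE)
  colnames(m) <- sprintf("c%d", 1:(2 * n))
  cells <- tibble::tibble(cell_id = colnames(m), sample_id = "s",
                          condition = "metastatic",
                          cell_type = rep(c("sender", "receiver"), each = n))
  db <- tibble::tibble(pair_id = "P1", ligand = "L", receptor = "R")
  tri <- screen_pairs(m, cells, db)
  expect_false(any(tri$sender == "sender" & tri$receiver == "receiver"))
  m2 <- m
  m2["L", 10] <- 1  # now exactly 10%
  tri2 <- screen_pairs(m2, cells, db)
  expect_true(any(tri2$sender == "sender" & tri2$receiver == "receiver"))
  # min_fraction 0 admits every pair with both genes present
  tri0 <- screen_pairs(m, cells, db, min_fraction = 0)
  expect_equal(nrow(tri0), 4)  # 2 sender x 2 receiver type combinations
  # absent genes are skipped with a log entry
  db2 <- dplyr::bind_rows(db, tibble::tibble(pair_id = "P2", ligand = "NOPE",
                                             receptor = "R"))
  expect_message(tri3 <- screen_pairs(m, cells, db2, min_fraction = 0), "skipped")
  expect_equal(nrow(attr(tri3, "skipped_pairs")), 1)
})

test_that("pair scores are products of group means", {
  fx <- lr_toy()
  s <- score_pair(fx$m, fx$cells, "L", "R", "sender", "receiver")
  expect_equal(s, 2 * (7 / 3))  # hand-computed means: 2 and 7/3
  # self-consistency: same type, same gene -> squared mean
  s2 <- score_pair(fx$m, fx$cells, "H", "H", "sender", "sender")
  expect_equal(s2, 1)
  expect_error(score_pair(fx$m, fx$cells, "L", "R", "sender", "missing_type"),
               class = "mn_bad_input")
})

test_that("permutation p-values hit the add-one floor and ceiling", {
  fx <- lr_toy()
  tri <- screen_pairs(fx$m, fx$cells, fx$db, min_fraction = 0)
  tri <- tri[tri$sender == "sender" & tri$receiver == "receiver", ]
  res <- lr_permutation_test(fx$m, fx$cells, tri, n_perm = 50, seed = 3)
  expect_true(all(res$p_val >= 1 / 51))
  # constant expression: every null equals observed -> p = 1
  db_h <- tibble::tibble(pair_id = "HH", ligand = "H", receptor = "H")
  tri_h <- screen_pairs(fx$m, fx$cells, db_h, min_fraction = 0)
  res_h <- lr_permutation_test(fx$m, fx$cells, tri_h, n_perm = 25, seed = 1)
  expect_true(all(res_h$p_val == 1))
})

test_that("exhaustive enumeration matches the closed-form oracle on the 6-cell toy", {
  fx <- lr_toy()
  tri <- screen_pairs(fx$m, fx$cells, fx$db, min_fraction = 0)
  tri <- tri[tri$sender == "sender" & tri$receiver == "receiver", ]
  res <- lr_permutation_test(fx$m, fx$cells, tri, exhaustive = TRUE)
  # oracle: enumerate the C(6,3) = 20 distinct sender-cell choices directly
  obs <- score_pair(fx$m, fx$cells, "L", "R", "sender", "receiver")
  combos <- utils::combn(6, 3)
  null_scores <- apply(combos, 2, function(ix) {
    mean(fx$m["L", ix]) * mean(fx$m["R", -ix])
  })
  # 20 distinct arrangements of the {3 sender, 3 receiver} label multiset
  expect_equal(res$n_perm[1], 20)
  p_oracle <- (1 + sum(null_scores >= obs)) / (1 + 20)
  expect_equal(res$p_val[1], p_oracle, tolerance = 1e-12)
})

test_that("results are reproducible from the seed and stable under cell doubling", {
  co <- small_cohort()
  db <- generate_lr_database(10, co$sim$genes, seed = 6)
  tri <- screen_pairs(co$norm, co$cells, db)
  tri <- head(tri, 20)
  r1 <- lr_permutation_test(co$norm, co$cells, tri, n_perm = 50, seed = 11)
  r2 <- lr_permutation_test(co$norm, co$cells, tri, n_perm = 50, seed = 11)
  expect_identical(r1$p_val, r2$p_val)
  expect_identical(r1$score, r2$score)
  # doubling every cell leaves observed scores unchanged
  m2 <- cbind(co$norm, `colnames<-`(co$norm, paste0(colnames(co$norm), "_dup")))
  cells2 <- dplyr::bind_rows(co$cells,
                             dplyr::mutate(co$cells, cell_id = paste0(cell_id, "_dup")))
  r3 <- lr_permutation_test(m2, cells2, tri, n_perm = 2, seed = 1)
  expect_equal(r3$score, r1$score, tolerance = 1e-12)
})

test_that("exclusive-ligand flags follow the marker Z cutoff", {
  mk <- tibble::tibble(gene = c("LIG1", "LIG2"), z = c(12, 0))
  fl <- flag_exclusive_ligands(mk, c("LIG1", "LIG2", "GONE"), z_cutoff = 3)
  expect_equal(fl$exclusive, c(TRUE, FALSE, FALSE))
  # planted tumor marker used as a ligand is flagged, a background gene is not
  co <- small_cohort()
  mk2 <- wilcoxon_markers(co$norm, co$cells$cell_type, "tumor")
  planted <- co$sim$truth$marker_genes$tumor[1]
  background <- setdiff(rownames(co$norm),
                        unlist(co$sim$truth$marker_genes))[1]
  fl2 <- flag_exclusive_ligands(mk2, c(planted, background), z_cutoff = 3)
  expect_true(fl2$exclusive[fl2$ligand == planted])
  expect_false(fl2$exclusive[fl2$ligand == background])
})
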