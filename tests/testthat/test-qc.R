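qc_fixture <- function(umis = c(599, 600, 601, 2000), dbl = c(0.1, 0.1, 0.1, 0.1)) {
  n <- length(umis)
  counts <- Matrix::Matrix(rbind(umis, matrix(0, 1, n)), sparse = TRUE)
  dimnames(counts) <- list(c("A", "B"), sprintf("c%d", seq_len(n)))
  cells <- tibble::tibble(cell_id = colnames(counts), sample_id = "s1",
                          condition = "metastatic", cell_type = "tumor",
                          doublet_score = dbl)
  list(counts = counts, cells = cells)
}

test_that("UMI threshold is strict below, inclusive at the cutoff", {
  fx <- qc_fixture()
  out <- filter_cells(fx$counts, fx$cells)
  expect_setequal(out$cells$cell_id, c("c2", "c3", "c4"))  # 599 removed, 600 kept
  expect_equal(out$audit$n_low_umi, 1L)
})

test_that("doublet threshold removes strictly above 0.4 only", {
  fx <- qc_fixture(umis = rep(1000, 3), dbl = c(0.39, 0.40, 0.41))
  out <- filter_cells(fx$counts, fx$cells)
  expect_setequal(out$cells$cell_id, c("c1", "c2"))  # 0.41 removed, 0.40 kept
  expect_equal(out$audit$n_doublet, 1L)
})

test_that("filtering is idempotent and the audit reconciles", {
  co <- small_cohort()
  out1 <- filter_cells(co$sim$counts, co$sim$cells)
  out2 <- filter_cells(out1$counts, out1$cells)
  expect_identical(as.matrix(out1$counts), as.matrix(out2$counts))
  expect_equal(sum(out2$audit$n_low_umi) + sum(out2$audit$n_doublet), 0)
  expect_equal(sum(out1$audit$n_input) - ncol(out1$counts),
               sum(out1$audit$n_input - out1$audit$n_retained))
})

test_that("empty input and missing doublet scores are handled explicitly", {
  fx <- qc_fixture()
  empty <- fx$counts[, integer(0)]
  out <- filter_cells(empty, fx$cells[integer(0), ])
  expect_equal(ncol(out$counts), 0)
  expect_equal(nrow(out$audit), 0)
  cells_nd <- dplyr::select(fx$cells, -"doublet_score")
  expect_error(filter_cells(fx$counts, cells_nd), class = "mn_missing_column")
})

comp_fixture <- function(props_a, props_b, n_per_sample = 100L) {
  # two cell types; proportion vectors give the T_cell share per sample
  rows <- list()
  for (i in seq_along(props_a)) {
    k <- round(props_a[i] * n_per_sample)
    rows[[paste0("a", i)]] <- tibble::tibble(
      cell_id = sprintf("a%d_%d", i, 1:n_per_sample),
      sample_id = paste0("sampleA", i), condition = "metastatic",
      cell_type = rep(c("T_cell", "other"), c(k, n_per_sample - k)))
  }
  for (i in seq_along(props_b)) {
    k <- round(props_b[i] * n_per_sample)
    rows[[paste0("b", i)]] <- tibble::tibble(
      cell_id = sprintf("b%d_%d", i, 1:n_per_sample),
      sample_id = paste0("sampleB", i), condition = "nonmetastatic",
      cell_type = rep(c("T_cell", "other"), c(k, n_per_sample - k)))
  }
  dplyr::bind_rows(rows)
}

test_that("proportions are computed over retained cells of each sample", {
  cells <- comp_fixture(0.10, 0.50)
  res <- composition_test(cells, "metastatic", "nonmetastatic", min_cells_per_sample = 1)
  p <- res$proportions
  expect_equal(p$proportion[p$sample_id == "sampleA1" & p$cell_type == "T_cell"], 0.10)
  expect_true(all(abs(tapply(p$proportion, p$sample_id, sum) - 1) < 1e-12))
})

test_that("identical proportion vectors give p = 1 and separated ones the exact p", {
  same <- composition_test(comp_fixture(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
                           "metastatic", "nonmetastatic", min_cells_per_sample = 1)
  expect_true(all(tidy(same)$p_val == 1))
  sep <- composition_test(comp_fixture(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)),
                          "metastatic", "nonmetastatic", min_cells_per_sample = 1)
  tt <- tidy(sep)
  expect_equal(tt$p_val[tt$cell_type == "T_cell"], 0.1)  # C(6,3) enumeration
  expect_true(all(tt$exact))
})

test_that("the comparison is invariant to group relabeling and cell order", {
  cells <- comp_fixture(c(0.15, 0.3, 0.22), c(0.4, 0.18, 0.55))
  r1 <- composition_test(cells, "metastatic", "nonmetastatic", min_cells_per_sample = 1)
  r2 <- composition_test(cells, "nonmetastatic", "metastatic", min_cells_per_sample = 1)
  expect_equal(tidy(r1)$p_val, tidy(r2)$p_val)
  r3 <- composition_test(cells[sample(nrow(cells)), ], "metastatic", "nonmetastatic",
                         min_cells_per_sample = 1)
  expect_equal(tidy(r1)$p_val, tidy(r3)$p_val)
})

test_that("the minimum-cell rule drops samples and the composition matches the cohort", {
  co <- small_cohort()
  res <- composition_test(co$cells, "metastatic", "nonmetastatic")
  expect_true(all(res$samples$n_total >= 40))
  expect_true(all(res$tests$p_val >= 0 & res$tests$p_val <= 1))
  # tiny sample below the cutoff is excluded
  cells <- dplyr::bind_rows(
    comp_fixture(c(0.1, 0.2), c(0.3, 0.4)),
    tibble::tibble(cell_id = "tiny1", sample_id = "tiny", condition = "metastatic",
                   cell_type = "T_cell"))
  res2 <- composition_test(cells, "metastatic", "nonmetastatic", min_cells_per_sample = 40)
  expect_false("tiny" %in% res2$proportions$sample_id)
})

test_that("exact composition p matches the enumeration oracle on random inputs", {
  set.seed(17)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- round(runif(na, 0.05, 0.9), 2)
    pb <- round(runif(nb, 0.05, 0.9), 2)
    if (anyDuplicated(c(pa, pb))) next
    res <- composition_test(comp_fixture(pa, pb), "metastatic", "nonmetastatic",
                            min_cells_per_sample = 1)
    tt <- tidy(res)
    expect_equal(tt$p_val[tt$cell_type == "T_cell"], enumeration_ranksum_p(pa, pb),
                 tolerance = 1e-12)
  }
})
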