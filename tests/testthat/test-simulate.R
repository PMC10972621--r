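test_that("generation is bit-identical under the same seed", {
  cfg <- sim_config(n_samples = c(metastatic = 2, nonmetastatic = 2, primary = 1),
                    cells_per_sample = c(50L, 70L), n_genes = 600L,
                    n_chromosomes = 4L, cnv_segments = tibble::tibble(
                      chromosome = "chr2", start_rank = 5L, end_rank = 60L,
                      copy_ratio = 2),
                    seed = 9L)
  a <- generate_sc_cohort(cfg)
  b <- generate_sc_cohort(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$de, b$truth$de)
})

test_that("tumor cells appear only where the design places them", {
  cfg <- sim_config(n_samples = c(metastatic = 2, nonmetastatic = 2),
                    cells_per_sample = c(50L, 60L), n_genes = 600L,
                    n_chromosomes = 4L,
                    cnv_segments = tibble::tibble(chromosome = "chr2",
                                                  start_rank = 5L, end_rank = 60L,
                                                  copy_ratio = 2),
                    tumor_fraction_metastatic = 0, seed = 4L)
  sim <- generate_sc_cohort(cfg)
  expect_false(any(sim$cells$cell_type == "tumor"))
  co <- small_cohort()
  nm <- co$sim$cells$condition == "nonmetastatic"
  expect_false(any(co$sim$cells$cell_type[nm] == "tumor"))
  expect_true(any(co$sim$cells$cell_type[!nm] == "tumor"))
})

test_that("degenerate compositions and bad CNV segments are rejected", {
  expect_error(sim_config(composition_shift = c(T_cell = 0, myeloid = 0,
                                                B_cell = 0, NK_cell = 0)),
               class = "mn_bad_config")
  expect_error(sim_config(cnv_segments = tibble::tibble(chromosome = "chr2",
                                                        start_rank = 1L,
                                                        end_rank = 9999L,
                                                        copy_ratio = 2)),
               class = "mn_bad_config")
  expect_error(sim_config(nb_dispersion = -1), class = "mn_bad_config")
})

test_that("per-gene count means converge to the configured expectations", {
  cfg <- sim_config(n_samples = c(metastatic = 1, nonmetastatic = 1),
                    cells_per_sample = c(5000L, 5000L), n_genes = 600L,
                    n_chromosomes = 4L,
                    cnv_segments = tibble::tibble(chromosome = "chr2",
                                                  start_rank = 5L, end_rank = 60L,
                                                  copy_ratio = 2),
                    doublet_rate = 0, seed = 31L)
  sim <- generate_sc_cohort(cfg)
  sel <- sim$cells$cell_type == "T_cell" & sim$cells$condition == "nonmetastatic"
  obs <- Matrix::rowMeans(sim$counts[, sel])
  prof <- expected_cell_means(sim, "T_cell", "nonmetastatic", library_size = 1)
  exp_mean <- prof * sum(obs) / sum(prof)  # scale by the realized mean library
  hi <- exp_mean >= 0.5
  rel <- abs(obs[hi] - exp_mean[hi]) / exp_mean[hi]
  expect_gte(mean(rel < 0.05), 0.9)
  expect_lt(mean(rel), 0.03)
})

test_that("composition recovery and ground-truth DE labels are consistent", {
  co <- small_cohort()
  sim <- co$sim
  cfg <- sim$config
  # non-tumor proportions in the nonmetastatic arm track the Dirichlet mean
  nm <- sim$cells[sim$cells$condition == "nonmetastatic", ]
  props <- prop.table(table(nm$cell_type))
  expected <- cfg$base_composition / sum(cfg$base_composition)
  expect_lt(max(abs(props[names(expected)] - expected)), 0.12)
  # DE ground truth = exactly the genes with configured fold != 1
  expect_setequal(sim$truth$de$symbol[sim$truth$de$comparison ==
                                        "metastatic_tumor_vs_primary_tumor"],
                  sim$truth$signature_genes)
  n_expected <- cfg$n_signature_genes + sum(cfg$cell_type_catalog$n_markers)
  expect_equal(nrow(sim$truth$de), n_expected)
  expect_true(all(sim$truth$de$fold_change != 1))
  # doublet scores separate constructed doublets from singlets at the 0.4 line
  dbl <- sim$truth$cells$is_doublet
  expect_true(all(sim$cells$doublet_score[dbl] > 0.4))
  expect_true(all(sim$cells$doublet_score[!dbl] <= 0.4))
})

test_that("bulk cohort generator obeys preconditions and plants the hazard", {
  expect_error(generate_bulk_cohort(0, c("A"), 2), class = "mn_bad_input")
  expect_error(generate_bulk_cohort(10, character(0), 2), class = "mn_bad_input")
  expect_error(generate_bulk_cohort(10, c("A"), -1), class = "mn_bad_input")
  b1 <- generate_bulk_cohort(50, c("A", "B"), 3, seed = 2)
  b2 <- generate_bulk_cohort(50, c("A", "B"), 3, seed = 2)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$survival, b2$survival)
  expect_true(all(b1$survival$event %in% c(0L, 1L)))
  # higher burden -> shorter expected event times at hazard ratio 3
  b <- generate_bulk_cohort(400, c("A", "B"), 3, seed = 8)
  hi <- b$truth$burden > quantile(b$truth$burden, 0.75)
  lo <- b$truth$burden < quantile(b$truth$burden, 0.25)
  expect_lt(median(b$survival$time[hi]), median(b$survival$time[lo]))
})

test_that("null bulk cohorts give calibrated log-rank rejections on burden quartiles", {
  rej <- vapply(1:200, function(i) {
    b <- generate_bulk_cohort(80, c("A", "B"), hazard_ratio = 1, seed = 1000 + i)
    q <- quantile(b$truth$burden, c(0.25, 0.75))
    surv <- b$survival
    surv$stratum <- ifelse(b$truth$burden >= q[2], "high",
                           ifelse(b$truth$burden <= q[1], "low", "mid"))
    surv <- surv[surv$stratum != "mid", ]
    logrank_test(surv, "high", "low")$p_val < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("ligand-receptor database generation is unique, disjoint and seeded", {
  genes <- sprintf("G%03d", 1:40)
  db <- generate_lr_database(1, genes, seed = 3)
  expect_equal(nrow(db), 1)
  expect_false(db$ligand == db$receptor)
  expect_identical(generate_lr_database(15, genes, seed = 5),
                   generate_lr_database(15, genes, seed = 5))
  db2 <- generate_lr_database(20, genes, seed = 1)
  expect_false(anyDuplicated(c(db2$ligand, db2$receptor)) > 0)
  expect_error(generate_lr_database(21, genes, seed = 1), class = "mn_bad_input")
})
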