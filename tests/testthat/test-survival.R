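test_that("the product-limit estimate matches hand computation", {
  surv <- tibble::tibble(patient_id = c("a", "b", "c"), time = c(1, 2, 3),
                         event = c(1, 0, 1), stratum = "all")
  km <- km_estimate(surv)
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival stays at 1
  cens <- dplyr::mutate(surv, event = 0)
  expect_true(all(km_estimate(cens)$survival == 1))
  # duplicating every patient leaves the curve unchanged
  dup <- dplyr::bind_rows(surv, dplyr::mutate(surv, patient_id = paste0(patient_id, "2")))
  expect_equal(km_estimate(dup)$survival, km$survival)
  expect_error(km_estimate(dplyr::mutate(surv, time = c(-1, 2, 3))),
               class = "mn_bad_input")
})

test_that("KM curves agree with the survival package on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(19)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    d <- tibble::tibble(patient_id = sprintf("p%02d", 1:n),
                        time = round(rexp(n, 0.1), 1),
                        event = rbinom(n, 1, 0.7), stratum = "all")
    km <- km_estimate(d)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    ours <- km$survival[match(fit$time, km$time)]
    expect_equal(ours, fit$surv, tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical strata and matches the moment oracle", {
  base <- tibble::tibble(patient_id = sprintf("a%d", 1:5),
                         time = c(2, 4, 4, 7, 9), event = c(1, 1, 0, 1, 0))
  both <- dplyr::bind_rows(dplyr::mutate(base, stratum = "x"),
                           dplyr::mutate(base, patient_id = paste0(patient_id, "b"),
                                         stratum = "y"))
  lr <- logrank_test(both, "x", "y")
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_val, 1)
  # small two-group fixture against the independent hypergeometric oracle
  d <- tibble::tibble(patient_id = sprintf("p%d", 1:6),
                      time = c(1, 3, 4, 5, 8, 9),
                      event = c(1, 1, 0, 1, 1, 0),
                      stratum = rep(c("high", "low"), each = 3))
  lr2 <- logrank_test(d, "high", "low")
  expect_equal(lr2$statistic,
               bruteforce_logrank(d$time, d$event, d$stratum), tolerance = 1e-12)
  # label swap invariance
  lr3 <- logrank_test(d, "low", "high")
  expect_equal(lr3$statistic, lr2$statistic, tolerance = 1e-12)
  expect_error(logrank_test(dplyr::mutate(d, event = 0), "high", "low"),
               class = "mn_no_events")
})

test_that("log-rank matches survival::survdiff on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(23)
  for (i in 1:10) {
    n <- sample(16:50, 1)
    d <- tibble::tibble(time = round(rexp(n, 0.1), 1),
                        event = rbinom(n, 1, 0.7),
                        stratum = sample(c("a", "b"), n, replace = TRUE))
    if (sum(d$event) == 0 || length(unique(d$stratum)) < 2) next
    lr <- logrank_test(d, "a", "b")
    ref <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = d, rho = 0)
    expect_equal(lr$statistic, ref$chisq, tolerance = 1e-8)
  }
})

test_that("the chi-square p is calibrated against label permutation on a null cohort", {
  b <- generate_bulk_cohort(120, c("A", "B"), hazard_ratio = 1, seed = 55)
  surv <- b$survival
  set.seed(7)
  p <- vapply(1:200, function(i) {
    surv$stratum <- sample(rep(c("x", "y"), each = 60))
    logrank_test(surv, "x", "y")$p_val
  }, numeric(1))
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.10)
})

test_that("a planted hazard ratio of 3 separates the quartile strata", {
  b <- generate_bulk_cohort(200, c("A", "B"), hazard_ratio = 3, seed = 13)
  sc <- score_signature(b$expr, gene_set("sig", c("A", "B")))
  st <- stratify_by_score(sc, 0.25)
  surv <- dplyr::inner_join(b$survival, st, by = c(patient_id = "id")) |>
    dplyr::filter(stratum != "excluded")
  km <- km_estimate(surv)
  # the high-burden stratum's curve lies below the low stratum's
  end_surv <- km |> dplyr::group_by(stratum) |> dplyr::summarise(s = min(survival))
  expect_lt(end_surv$s[end_surv$stratum == "high"],
            end_surv$s[end_surv$stratum == "low"])
  expect_lt(logrank_test(surv, "high", "low")$p_val, 0.001)
})
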