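# independent brute-force oracles used across test files

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
enumeration_ranksum_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(N, n1)
  us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force BH step-up
bruteforce_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# log-rank statistic from hypergeometric moments, written independently
bruteforce_logrank <- function(time, event, grp) {
  ts <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == levels(factor(grp))[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == levels(factor(grp))[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# small cached cohorts shared between test files
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    cfg <- sim_config(n_samples = c(metastatic = 3, nonmetastatic = 3, primary = 2),
                      cells_per_sample = c(80L, 120L), n_genes = 600L,
                      n_chromosomes = 6L,
                      cnv_segments = tibble::tibble(chromosome = "chr2",
                                                    start_rank = 10L, end_rank = 90L,
                                                    copy_ratio = 2),
                      seed = 42L)
    sim <- generate_sc_cohort(cfg)
    qc <- filter_cells(sim$counts, sim$cells)
    .cohort_cache$small <- list(sim = sim, counts = qc$counts, cells = qc$cells,
                                norm = normalize_counts(qc$counts))
  }
  .cohort_cache$small
}
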