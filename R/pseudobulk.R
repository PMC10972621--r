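#' Build per-sample pseudobulk ("mini-bulk") count profiles
#'
#' Sums raw counts over all cells of one cell type within each sample.
#' Samples contributing fewer than `min_cells` cells of that type are
#' excluded (and recorded), the rule used for sample-level differential
#' expression.
#'
#' @param counts Sparse genes x cells count matrix (raw counts).
#' @param cells Cell tibble with `cell_id`, `sample_id`, `condition`,
#'   `cell_type`.
#' @param cell_type The cell type to aggregate.
#' @param min_cells Minimum cells per sample (default 10).
#' @return A `mn_pseudobulk` object: `counts` (genes x samples integer
#'   matrix), `samples` (tibble `sample_id`, `condition`, `n_cells`) and
#'   `excluded` (same shape, the dropped samples).
#' @export
make_pseudobulk <- function(counts, cells, cell_type, min_cells = 10L) {
  counts <- as_count_matrix(counts)
  cells <- assert_aligned(counts, tibble::as_tibble(cells))
  if (!cell_type %in% cells$cell_type) {
    stop_mn(sprintf("cell type '%s' not present in the cell table", cell_type),
            "mn_bad_input")
  }
  sel <- cells$cell_type == cell_type & !is.na(cells$cell_type)
  tab <- cells[sel, ] |>
    dplyr::count(.data$sample_id, .data$condition, name = "n_cells")
  keep <- tab |> dplyr::filter(.data$n_cells >= min_cells)
  dropped <- tab |> dplyr::filter(.data$n_cells < min_cells)
  if (nrow(keep) == 0) {
    stop_mn(sprintf("no sample has >= %d cells of type '%s'", min_cells, cell_type),
            "mn_bad_input")
  }
  pb <- vapply(keep$sample_id, function(s) {
    idx <- which(sel & cells$sample_id == s)
    as.numeric(Matrix::rowSums(counts[, idx, drop = FALSE]))
  }, numeric(nrow(counts)))
  pb <- matrix(as.integer(round(pb)), nrow = nrow(counts),
               dimnames = list(rownames(counts), keep$sample_id))
  structure(list(counts = pb, samples = keep, excluded = dropped,
                 cell_type = cell_type, min_cells = min_cells),
            class = "mn_pseudobulk")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio of its count to the
#' gene's geometric mean, computed over genes with all-positive counts.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of size factors (geometric mean 1 is not imposed;
#'   ratios to a common reference are).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop_mn("no gene has positive counts in every sample", "mn_bad_input")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - geo)))
}

# Newton inversion of the trigamma function (for the moderation prior df)
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# method-of-moments dispersion per gene, moderated toward a smooth
# mean-dispersion trend (loess on the log scale, median fallback) with an
# empirical-Bayes prior weight: the prior df d0 is moment-matched from the
# spread of log(raw/trend) around the trend, and the posterior dispersion is
# the df-weighted arithmetic combination (d0*trend + dg*raw)/(d0 + dg)
estimate_dispersions <- function(q, group, n_samples, mean_inv_sf) {
  m <- rowMeans(q)
  dg <- max(1, n_samples - 2)
  resid_var <- vapply(seq_len(nrow(q)), function(g) {
    r <- unlist(lapply(split(q[g, ], group), function(v) v - mean(v)))
    sum(r^2) / dg
  }, numeric(1))
  raw <- pmax((resid_var - m * mean_inv_sf) / m^2, 1e-8)
  use <- m > 0.5 & raw > 1e-7
  trend <- rep(if (any(use)) stats::median(raw[use]) else 0.1, length(raw))
  if (sum(use) >= 20) {
    td <- data.frame(lmean = log(m[use]), ldisp = log(raw[use]))
    fit <- try(stats::loess(ldisp ~ lmean, data = td, span = 0.6, degree = 1,
                            control = stats::loess.control(surface = "direct")),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      pred <- try(stats::predict(fit, newdata = data.frame(lmean = log(pmax(m, 1e-8)))),
                  silent = TRUE)
      if (!inherits(pred, "try-error")) {
        ok <- is.finite(pred)
        trend[ok] <- exp(pred[ok])
      }
    }
  }
  excess <- if (sum(use) >= 20) {
    stats::var(log(raw[use] / trend[use])) - trigamma(dg / 2)
  } else {
    NA_real_
  }
  d0 <- if (!is.finite(excess) || excess <= 0) 100 else min(100, 2 * trigamma_inverse(excess))
  disp <- (d0 * trend + dg * raw) / (d0 + dg)
  pmin(pmax(disp, 1e-8), 10)
}

#' Pseudobulk negative-binomial differential expression
#'
#' A simplified sample-level NB Wald pipeline: median-of-ratios size
#' factors over the combined matrix; per-gene method-of-moments dispersion
#' moderated toward a smooth mean-dispersion trend with an empirical-Bayes
#' prior weight moment-matched from the spread of gene-wise dispersions
#' around the trend; an NB GLM of counts on the group indicator with log
#' size-factor offset; a Wald test of the group coefficient;
#' Benjamini-Hochberg across tested genes.  Genes with zero counts
#' everywhere are reported untested.
#'
#' @param pb_a,pb_b `mn_pseudobulk` objects (or plain genes x samples count
#'   matrices) for the two groups; gene rows must match.
#' @return A `mn_de` object whose `results` tibble has one row per gene:
#'   `gene`, `base_mean`, `log2_fc` (B relative to A), `stat`, `p_val`,
#'   `p_adj`, `tested`.
#' @export
pseudobulk_de <- function(pb_a, pb_b) {
  get_counts <- function(x) if (inherits(x, "mn_pseudobulk")) x$counts else as.matrix(x)
  a <- get_counts(pb_a)
  b <- get_counts(pb_b)
  if (nrow(a) != nrow(b)) stop_mn("gene rows of the two groups differ", "mn_dimension_mismatch")
  if (ncol(a) < 2 || ncol(b) < 2) stop_mn("need >= 2 samples per group", "mn_bad_input")
  counts <- cbind(a, b)
  group <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("A", "B"))
  n_samples <- ncol(counts)
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")

  tested <- rowSums(counts) > 0
  disp <- rep(NA_real_, nrow(counts))
  disp[tested] <- estimate_dispersions(q[tested, , drop = FALSE], group, n_samples,
                                       mean(1 / sf))

  res <- tibble::tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = rowMeans(q),
    log2_fc = NA_real_, stat = NA_real_, p_val = NA_real_,
    tested = tested, dispersion = disp
  )
  off <- log(sf)
  for (g in which(tested)) {
    fit <- try(suppressWarnings(
      stats::glm(counts[g, ] ~ group + offset(off),
                 family = MASS::negative.binomial(theta = 1 / disp[g]),
                 control = list(maxit = 100))
    ), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    sm <- summary(fit, dispersion = 1)$coefficients
    if (nrow(sm) < 2) next
    beta <- sm["groupB", "Estimate"]
    se <- sm["groupB", "Std. Error"]
    res$log2_fc[g] <- beta / log(2)
    res$stat[g] <- beta / se
    res$p_val[g] <- 2 * stats::pnorm(-abs(beta / se))
  }
  ok <- !is.na(res$p_val)
  res$p_adj <- NA_real_
  res$p_adj[ok] <- benjamini_hochberg(res$p_val[ok])
  structure(list(results = res,
                 samples = tibble::tibble(sample_id = colnames(counts),
                                          group = as.character(group),
                                          size_factor = sf)),
            class = "mn_de")
}

#' @export
print.mn_de <- function(x, ...) {
  cat(sprintf("<mn_de> %d genes tested (%d samples)\n",
              sum(x$results$tested), nrow(x$samples)))
  print(dplyr::arrange(x$results, .data$p_val))
  invisible(x)
}
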