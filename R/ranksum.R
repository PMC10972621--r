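#' Two-sided Wilcoxon rank-sum test with signed-Z conversion
#'
#' The shared rank-sum routine behind marker detection, composition tests and
#' signature comparisons.  When both groups have at most `max_exact`
#' observations and the data carry no ties, the exact null distribution of the
#' rank-sum statistic is used; otherwise the normal approximation with midrank
#' tie correction and continuity correction.  The signed Z score is
#' `sign(mean rank difference) * qnorm(1 - p/2)`, so `|Z|` and `p` are always
#' consistent.
#'
#' @param x,y Numeric vectors, the two groups.
#' @param max_exact Largest per-group size for which the exact distribution is
#'   used (ties always force the approximation).
#' @return A list with elements `p` (two-sided p-value), `z` (signed Z),
#'   `statistic` (the Mann-Whitney U for `x`), `exact` (logical) and
#'   `mean_rank_diff`.
#' @examples
#' rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p  # exact: 0.1
#' @export
rank_sum_test <- function(x, y, max_exact = 10) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop_mn("both groups must be non-empty", "mn_bad_input")
  v <- c(x, y)
  if (any(!is.finite(v))) stop_mn("rank-sum input must be finite", "mn_bad_input")
  r <- rank(v)
  r1 <- sum(r[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean_rank_diff <- r1 / n1 - (sum(r) - r1) / n2
  ties <- anyDuplicated(v) > 0
  exact <- (n1 <= max_exact && n2 <= max_exact && !ties)

  if (all(v == v[1])) {
    return(list(p = 1, z = 0, statistic = U, exact = FALSE, mean_rank_diff = 0))
  }

  if (exact) {
    lo <- stats::pwilcox(U, n1, n2)
    hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
  } else {
    N <- n1 + n2
    tie_counts <- tabulate(match(v, unique(v)))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_counts^3 - tie_counts) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(list(p = 1, z = 0, statistic = U, exact = FALSE, mean_rank_diff = mean_rank_diff))
    }
    d <- U - mu
    cc <- if (d > 0) 0.5 else if (d < 0) -0.5 else 0
    zz <- (d - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zz)))
  }
  z_abs <- stats::qnorm(p / 2, lower.tail = FALSE)
  z <- sign(mean_rank_diff) * z_abs
  list(p = p, z = z, statistic = U, exact = exact, mean_rank_diff = mean_rank_diff)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the standard step-up procedure
#' (via [stats::p.adjust()]): adjusted values are monotone in the sorted
#' order and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) stop_mn("p-values must be numeric", "mn_bad_input")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_mn("p-values must lie in [0, 1]", "mn_bad_input")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon marker detection for one cluster
#'
#' For every gene, compares normalized expression in the target cluster
#' against all other cells with a two-sided rank-sum test, converts the
#' p-value to a signed Z score, and adjusts across genes with
#' Benjamini-Hochberg.  Genes with `z` above a cutoff (3 in the default
#' downstream filtering) are the cluster's markers.
#'
#' @param norm Normalized genes x cells matrix (see [normalize_counts()]).
#' @param labels Character vector of cluster labels, one per column of `norm`.
#' @param target Cluster label whose markers are sought.
#' @return A tibble with one row per gene: `gene`, `z`, `p_val`, `p_adj`,
#'   `frac_in`, `frac_out` (fraction of cells expressing), `mean_in`,
#'   `mean_out` (mean normalized expression) and `log2_fc`.  Constant genes
#'   are flagged in the `constant` column with `z = 0`, `p = 1`.
#' @export
wilcoxon_markers <- function(norm, labels, target) {
  if (length(labels) != ncol(norm)) {
    stop_mn("labels must have one entry per cell", "mn_dimension_mismatch")
  }
  in_idx <- which(labels == target)
  out_idx <- which(labels != target)
  if (length(in_idx) < 2 || length(out_idx) < 2) {
    stop_mn(sprintf("cluster '%s' and its complement must each have >= 2 cells", target),
            "mn_bad_input")
  }
  X <- as.matrix(norm)
  n_genes <- nrow(X)
  z <- p <- numeric(n_genes)
  constant <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    xi <- X[g, in_idx]
    yi <- X[g, out_idx]
    if (all(c(xi, yi) == xi[1])) {
      z[g] <- 0
      p[g] <- 1
      constant[g] <- TRUE
    } else {
      rs <- rank_sum_test(xi, yi)
      z[g] <- rs$z
      p[g] <- rs$p
    }
  }
  mean_in <- rowMeans(X[, in_idx, drop = FALSE])
  mean_out <- rowMeans(X[, out_idx, drop = FALSE])
  eps <- 1e-9
  tibble::tibble(
    gene = rownames(X) %||% as.character(seq_len(n_genes)),
    z = z,
    p_val = p,
    p_adj = benjamini_hochberg(p),
    frac_in = rowMeans(X[, in_idx, drop = FALSE] > 0),
    frac_out = rowMeans(X[, out_idx, drop = FALSE] > 0),
    mean_in = mean_in,
    mean_out = mean_out,
    log2_fc = log2((expm1(mean_in) + eps) / (expm1(mean_out) + eps)),
    constant = constant
  )
}
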