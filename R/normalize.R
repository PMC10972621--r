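#' Library-size normalization
#'
#' Scales every cell to a common total (`scale` counts per cell) and, by
#' default, applies `log1p`.  This is the de-facto convention of the droplet
#' single-cell toolchain: entry `= log1p(count / cell_total * scale)` with the
#' log flag set, the scaled value otherwise, so each column of the pre-log
#' matrix sums to `scale`.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale Target per-cell total (default 10,000).
#' @param log_transform Apply `log1p` after scaling (default `TRUE`).
#' @return A `dgCMatrix` with attributes `scale` and `log` recording the
#'   transform.
#' @export
normalize_counts <- function(counts, scale = 1e4, log_transform = TRUE) {
  m <- as_count_matrix(counts)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0] %||% which(totals == 0)
    stop_mn(sprintf("cells with zero total counts cannot be normalized: %s",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "mn_zero_cell")
  }
  if (scale <= 0) stop_mn("scale must be positive", "mn_bad_input")
  out <- m %*% Matrix::Diagonal(x = scale / totals)
  dimnames(out) <- dimnames(m)
  if (log_transform) out@x <- log1p(out@x)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "scale") <- scale
  attr(out, "log") <- log_transform
  out
}
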