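# internal helpers shared across modules

stop_mn <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "metaniche_error"), ...)
}

# coerce a counts-like input to dgCMatrix, checking non-negativity
as_count_matrix <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop_mn("count matrix contains negative entries", "mn_bad_counts")
  m
}

assert_aligned <- function(mat, cells) {
  if (is.null(colnames(mat))) stop_mn("matrix has no cell (column) names", "mn_bad_input")
  if (!all(colnames(mat) == cells$cell_id)) {
    if (!setequal(colnames(mat), cells$cell_id)) {
      stop_mn("matrix columns and cell table do not describe the same cells",
              "mn_dimension_mismatch")
    }
    cells <- cells[match(colnames(mat), cells$cell_id), , drop = FALSE]
  }
  cells
}

# all distinct permutations of a label multiset (small n only)
multiset_permutations <- function(labels, max_n = 1e5) {
  n <- length(labels)
  counts <- table(labels)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (n_distinct > max_n) {
    stop_mn(sprintf("%.0f distinct label arrangements exceed the enumeration limit", n_distinct),
            "mn_enumeration_limit")
  }
  out <- vector("list", 0)
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      rec(c(prefix, u), remaining[-i])
    }
  }
  rec(character(0), sort(labels))
  out
}
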