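#' Gene-set signature score
#'
#' The unweighted mean of normalized expression over the set's member genes
#' present in the matrix, per column (cell or bulk sample).  Membership is
#' resolved by row name (gene symbol); absent members are reported, never
#' turned into `NaN`.
#'
#' @param norm Normalized genes x units matrix (cells, or bulk samples).
#' @param set A [gene_set()] or character vector of gene symbols.
#' @return A tibble (`id`, `score`, `n_members_used`) with attribute
#'   `missing_members`.
#' @export
score_signature <- function(norm, set) {
  name <- if (inherits(set, "gene_set")) set$name else "signature"
  members <- if (inherits(set, "gene_set")) set$genes else unique(as.character(set))
  present <- intersect(members, rownames(norm))
  if (length(present) == 0) {
    stop_mn(sprintf("no member of gene set '%s' is present in the matrix", name),
            "mn_empty_signature")
  }
  missing <- setdiff(members, present)
  if (length(missing)) {
    rlang::inform(sprintf("gene set '%s': %d of %d members absent from the matrix",
                          name, length(missing), length(members)))
  }
  sub <- norm[present, , drop = FALSE]
  scores <- as.numeric(Matrix::colMeans(sub))
  out <- tibble::tibble(
    id = colnames(norm) %||% as.character(seq_len(ncol(norm))),
    score = scores,
    n_members_used = length(present)
  )
  attr(out, "missing_members") <- missing
  attr(out, "set_name") <- name
  out
}

#' Compare signature scores between two groups
#'
#' Two-sided Wilcoxon rank-sum comparison of signature scores between two
#' conditions, at the cell level or aggregated to per-sample means first
#' (figure legends in this literature use both units, so the unit is an
#' explicit argument).  With a `within` stratification (e.g. cell type), one
#' comparison is run per stratum and Benjamini-Hochberg is applied across
#' the family.
#'
#' @param scores Tibble from [score_signature()] (`id`, `score`).
#' @param cells Cell tibble keyed by `cell_id` carrying the grouping columns.
#' @param group_a,group_b Values of `group_col` to compare.
#' @param group_col Grouping column (default `"condition"`).
#' @param unit `"cell"` (each cell is an observation) or `"sample"`
#'   (per-sample mean scores are the observations).
#' @param within Optional column name: run one comparison per level.
#' @return A tibble with one row per comparison: group sizes, medians, IQRs,
#'   raw and BH-adjusted p.  Comparisons with a group of size < 2 are
#'   skipped with a warning.
#' @export
compare_signature <- function(scores, cells, group_a, group_b,
                              group_col = "condition", unit = c("cell", "sample"),
                              within = NULL) {
  unit <- match.arg(unit)
  cells <- tibble::as_tibble(cells)
  d <- dplyr::inner_join(scores, cells, by = c(id = "cell_id")) |>
    dplyr::filter(.data[[group_col]] %in% c(group_a, group_b))
  if (unit == "sample") {
    grp <- c("sample_id", group_col, within)
    d <- d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
  }
  strata <- if (is.null(within)) list(`all` = d) else split(d, d[[within]])
  rows <- purrr::imap(strata, function(dd, nm) {
    a <- dd$score[dd[[group_col]] == group_a]
    b <- dd$score[dd[[group_col]] == group_b]
    if (length(a) < 2 || length(b) < 2) {
      rlang::warn(sprintf("comparison '%s' skipped: a group has fewer than 2 observations", nm))
      return(NULL)
    }
    rs <- rank_sum_test(a, b)
    tibble::tibble(
      comparison = nm, unit = unit, n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      iqr_a = stats::IQR(a), iqr_b = stats::IQR(b),
      statistic = rs$statistic, p_val = rs$p, exact = rs$exact
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop_mn("no comparison could be run", "mn_bad_input")
  out$p_adj <- benjamini_hochberg(out$p_val)
  out
}
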