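#' Cell-level quality filtering
#'
#' Removes low-quality cells: fewer than `min_umi` total UMIs ("fewer than"
#' is strict, so a cell at exactly `min_umi` is retained) or a doublet score
#' strictly above `max_doublet`.  A missing `doublet_score` column is an
#' error, never silently treated as a pass.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param cells Cell tibble with `cell_id`, `sample_id`, `doublet_score`
#'   (and optionally `total_umis`, recomputed here).
#' @param min_umi Minimum total UMIs (default 600).
#' @param max_doublet Maximum tolerated doublet score (default 0.4).
#' @return A list with the filtered `counts` and `cells`, and `audit`: one
#'   row per sample with cells removed per criterion.  Idempotent.
#' @export
filter_cells <- function(counts, cells, min_umi = 600L, max_doublet = 0.4) {
  counts <- as_count_matrix(counts)
  cells <- tibble::as_tibble(cells)
  if (!"doublet_score" %in% names(cells) || any(is.na(cells$doublet_score))) {
    stop_mn("filter_cells requires a complete doublet_score column", "mn_missing_column")
  }
  if (ncol(counts) == 0) {
    return(list(counts = counts, cells = cells,
                audit = tibble::tibble(sample_id = character(), n_input = integer(),
                                       n_low_umi = integer(), n_doublet = integer(),
                                       n_retained = integer())))
  }
  cells <- assert_aligned(counts, cells)
  cells$total_umis <- as.integer(Matrix::colSums(counts))
  low_umi <- cells$total_umis < min_umi
  doublet <- cells$doublet_score > max_doublet
  keep <- !low_umi & !doublet
  audit <- cells |>
    dplyr::mutate(low_umi = low_umi, doublet = doublet, kept = keep) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_input = dplyr::n(),
                     n_low_umi = sum(.data$low_umi),
                     n_doublet = sum(.data$doublet),
                     n_retained = sum(.data$kept),
                     .groups = "drop")
  list(counts = counts[, keep, drop = FALSE],
       cells = cells[keep, , drop = FALSE],
       audit = audit)
}

#' Per-sample cell-type composition comparison between conditions
#'
#' Computes each sample's cell-type proportions over its retained cells
#' (samples with fewer than `min_cells_per_sample` cells are dropped, the
#' rule used when re-analysing lineage subsets), then compares the per-sample
#' proportions of every cell type between the two conditions with a
#' two-sided Wilcoxon rank-sum test — exact when both arms have at most 10
#' samples and no tied proportions, normal approximation with tie correction
#' otherwise.
#'
#' @param cells Cell tibble with `sample_id`, `condition`, `cell_type`.
#' @param group_a,group_b Condition labels to compare.
#' @param min_cells_per_sample Minimum retained cells for a sample to enter
#'   the comparison (default 40).
#' @return A `mn_composition` object: list with `proportions` (tibble
#'   `sample_id`, `condition`, `cell_type`, `n_cells`, `proportion`) and
#'   `tests` (one row per cell type with group sizes, medians, quartiles,
#'   rank-sum statistic and two-sided p).
#' @export
composition_test <- function(cells, group_a, group_b, min_cells_per_sample = 40L) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("sample_id", "condition", "cell_type") %in% names(cells)))
  cells <- cells |> dplyr::filter(.data$condition %in% c(group_a, group_b),
                                  !is.na(.data$cell_type))
  sizes <- cells |> dplyr::count(.data$sample_id, .data$condition, name = "n_total")
  kept_samples <- sizes |> dplyr::filter(.data$n_total >= min_cells_per_sample)
  if (!any(kept_samples$condition == group_a) || !any(kept_samples$condition == group_b)) {
    stop_mn("each condition needs at least one sample after the minimum-cell rule",
            "mn_bad_input")
  }
  cells <- cells |> dplyr::semi_join(kept_samples, by = "sample_id")
  props <- cells |>
    dplyr::count(.data$sample_id, .data$condition, .data$cell_type, name = "n_cells") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("sample_id"), !!rlang::sym("condition")),
                    !!rlang::sym("cell_type"), fill = list(n_cells = 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
  absent <- props |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(tot = sum(.data$n_cells), .groups = "drop") |>
    dplyr::filter(.data$tot == 0)
  if (nrow(absent)) {
    rlang::warn(sprintf("cell types absent from every sample excluded: %s",
                        paste(absent$cell_type, collapse = ", ")))
    props <- props |> dplyr::filter(!.data$cell_type %in% absent$cell_type)
  }
  tests <- props |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(d, key) {
      a <- d$proportion[d$condition == group_a]
      b <- d$proportion[d$condition == group_b]
      rs <- rank_sum_test(a, b)
      tibble::tibble(
        n_a = length(a), n_b = length(b),
        median_a = stats::median(a), median_b = stats::median(b),
        q1_a = unname(stats::quantile(a, 0.25)), q3_a = unname(stats::quantile(a, 0.75)),
        q1_b = unname(stats::quantile(b, 0.25)), q3_b = unname(stats::quantile(b, 0.75)),
        statistic = rs$statistic, p_val = rs$p, exact = rs$exact
      )
    }) |>
    dplyr::ungroup()
  structure(list(proportions = props, tests = tests,
                 groups = c(group_a, group_b),
                 min_cells_per_sample = min_cells_per_sample,
                 samples = kept_samples),
            class = "mn_composition")
}

#' @export
print.mn_composition <- function(x, ...) {
  cat(sprintf("<mn_composition> %s vs %s: %d samples, %d cell types\n",
              x$groups[1], x$groups[2], nrow(x$samples), nrow(x$tests)))
  print(x$tests)
  invisible(x)
}
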