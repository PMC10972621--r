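#' Derive a metastatic tumor-cell gene signature
#'
#' Runs the Wilcoxon-Z marker test twice — metastatic tumor cells against
#' primary tumor cells, and metastatic tumor cells against all non-malignant
#' cells — and intersects the genes whose signed Z exceeds `z_cutoff` in
#' both.  The second comparison operationalizes "exclusively expressed in
#' tumor cells"; an optional extra filter drops genes expressed in more than
#' `max_nonmalignant_fraction` of non-malignant cells.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell tibble with `cell_id`, `condition`
#'   (`metastatic`/`nonmetastatic`/`primary`) and `cell_type` (tumor cells
#'   labeled `tumor_label`).
#' @param z_cutoff Signed-Z threshold applied to both comparisons
#'   (default 10).
#' @param tumor_label Label of malignant cells (default `"tumor"`).
#' @param max_nonmalignant_fraction Optional exclusivity filter (disabled by
#'   default, `Inf`).
#' @return A `mn_signature_derivation` object: `signature` ([gene_set()],
#'   possibly empty-with-warning), `provenance` (per-gene Z in each
#'   comparison and pass flags), the two full marker tables, `z_cutoff`.
#' @export
derive_signature <- function(norm, cells, z_cutoff = 10, tumor_label = "tumor",
                             max_nonmalignant_fraction = Inf) {
  cells <- assert_aligned(norm, tibble::as_tibble(cells))
  is_tumor <- cells$cell_type == tumor_label & !is.na(cells$cell_type)
  grp_a <- dplyr::case_when(
    is_tumor & cells$condition == "metastatic" ~ "met_tumor",
    is_tumor & cells$condition == "primary" ~ "primary_tumor",
    TRUE ~ NA_character_
  )
  grp_b <- dplyr::if_else(is_tumor & cells$condition == "metastatic",
                          "met_tumor",
                          dplyr::if_else(!is_tumor, "non_malignant", NA_character_))
  if (sum(grp_a == "met_tumor", na.rm = TRUE) < 2 ||
      sum(grp_a == "primary_tumor", na.rm = TRUE) < 2 ||
      sum(grp_b == "non_malignant", na.rm = TRUE) < 2) {
    stop_mn("metastatic tumor, primary tumor and non-malignant groups must all be non-empty",
            "mn_bad_input")
  }
  sel_a <- !is.na(grp_a)
  mk_a <- wilcoxon_markers(norm[, sel_a, drop = FALSE], grp_a[sel_a], "met_tumor")
  sel_b <- !is.na(grp_b)
  mk_b <- wilcoxon_markers(norm[, sel_b, drop = FALSE], grp_b[sel_b], "met_tumor")

  prov <- tibble::tibble(
    gene = mk_a$gene,
    z_vs_primary = mk_a$z,
    z_vs_nonmalignant = mk_b$z[match(mk_a$gene, mk_b$gene)],
    frac_nonmalignant = mk_b$frac_out[match(mk_a$gene, mk_b$gene)]
  ) |>
    dplyr::mutate(
      pass_vs_primary = .data$z_vs_primary > z_cutoff,
      pass_vs_nonmalignant = .data$z_vs_nonmalignant > z_cutoff,
      pass_exclusivity = .data$frac_nonmalignant <= max_nonmalignant_fraction,
      in_signature = .data$pass_vs_primary & .data$pass_vs_nonmalignant &
        .data$pass_exclusivity
    )
  members <- prov$gene[prov$in_signature]
  if (length(members) == 0) {
    rlang::warn(sprintf("no gene exceeds Z = %g in both comparisons; empty signature", z_cutoff))
    sig <- structure(list(name = "metastatic_signature", genes = character(0)),
                     class = "gene_set")
  } else {
    sig <- gene_set("metastatic_signature", members)
  }
  structure(list(signature = sig, provenance = prov,
                 markers_vs_primary = mk_a, markers_vs_nonmalignant = mk_b,
                 z_cutoff = z_cutoff),
            class = "mn_signature_derivation")
}

#' @export
print.mn_signature_derivation <- function(x, ...) {
  cat(sprintf("<mn_signature_derivation> Z > %g in both comparisons: %d genes\n",
              x$z_cutoff, length(x$signature$genes)))
  invisible(x)
}

#' Stratify patients by signature score quantiles
#'
#' Assigns the top `quantile` fraction of patients by score to the `high`
#' stratum, the bottom fraction to `low`, and the middle mass to
#' `excluded` (the top/bottom-25% rule by default).  Boundary ties are
#' broken deterministically by stable patient-id order, with the boundary
#' patient assigned to the stratum.
#'
#' @param bulk_scores Tibble (`id`, `score`) from [score_signature()] on a
#'   bulk matrix.
#' @param quantile Tail fraction in (0, 0.5] (default 0.25).
#' @return A tibble (`id`, `score`, `stratum`) with attribute `degenerate`
#'   set when all scores are equal.
#' @export
stratify_by_score <- function(bulk_scores, quantile = 0.25) {
  if (quantile <= 0 || quantile > 0.5) stop_mn("quantile must lie in (0, 0.5]", "mn_bad_input")
  d <- tibble::as_tibble(bulk_scores)
  n <- nrow(d)
  if (n < 4) stop_mn("need at least 4 patients to stratify", "mn_bad_input")
  k <- floor(quantile * n)
  if (k < 1) stop_mn("quantile too small: empty strata", "mn_bad_input")
  ord <- order(d$score, d$id)
  stratum <- rep("excluded", n)
  stratum[ord[seq_len(k)]] <- "low"
  stratum[ord[n - k + seq_len(k)]] <- "high"
  degenerate <- length(unique(d$score)) == 1
  if (degenerate) {
    rlang::warn("all scores are equal; strata assigned by the documented id-order tie rule")
  }
  out <- d |> dplyr::mutate(stratum = stratum)
  attr(out, "degenerate") <- degenerate
  attr(out, "quantile") <- quantile
  out
}
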