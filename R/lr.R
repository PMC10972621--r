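# per-type expression fraction and mean for a set of genes
type_summaries <- function(norm, genes, labels) {
  types <- sort(unique(labels))
  sub <- norm[genes, , drop = FALSE]
  frac <- vapply(types, function(tp) {
    Matrix::rowMeans(sub[, labels == tp, drop = FALSE] > 0)
  }, numeric(length(genes)))
  mean_ <- vapply(types, function(tp) {
    Matrix::rowMeans(sub[, labels == tp, drop = FALSE])
  }, numeric(length(genes)))
  frac <- matrix(frac, nrow = length(genes), dimnames = list(genes, types))
  mean_ <- matrix(mean_, nrow = length(genes), dimnames = list(genes, types))
  list(frac = frac, mean = mean_, types = types)
}

#' Screen ligand-receptor pairs by expression fraction
#'
#' A (pair, sender, receiver) triple is admissible when the ligand is
#' expressed (normalized value > 0) in at least `min_fraction` of the sender
#' cells and the receptor in at least `min_fraction` of the receiver cells
#' (10% by default).  Pairs whose genes are absent from the matrix are
#' skipped and recorded.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell tibble with `cell_id` and `cell_type`.
#' @param db Ligand-receptor tibble (`pair_id`, `ligand`, `receptor`).
#' @param min_fraction Expression-fraction threshold (default 0.10).
#' @return A tibble of admissible triples: `pair_id`, `ligand`, `receptor`,
#'   `sender`, `receiver`, `ligand_frac`, `receptor_frac`; attribute
#'   `skipped_pairs` lists pairs with absent genes.
#' @export
screen_pairs <- function(norm, cells, db, min_fraction = 0.10) {
  cells <- assert_aligned(norm, tibble::as_tibble(cells))
  labels <- cells$cell_type
  if (any(is.na(labels))) stop_mn("all cells need a cell_type for LR screening", "mn_bad_input")
  db <- tibble::as_tibble(db)
  present <- db$ligand %in% rownames(norm) & db$receptor %in% rownames(norm)
  skipped <- db[!present, , drop = FALSE]
  if (nrow(skipped)) {
    rlang::inform(sprintf("%d pairs skipped: gene absent from the matrix", nrow(skipped)))
  }
  db <- db[present, , drop = FALSE]
  genes <- unique(c(db$ligand, db$receptor))
  ts <- type_summaries(norm, genes, labels)
  combos <- tidyr::expand_grid(db, sender = ts$types, receiver = ts$types)
  lf <- ts$frac[cbind(combos$ligand, combos$sender)]
  rf <- ts$frac[cbind(combos$receptor, combos$receiver)]
  out <- combos |>
    dplyr::mutate(ligand_frac = lf, receptor_frac = rf) |>
    dplyr::filter(.data$ligand_frac >= min_fraction, .data$receptor_frac >= min_fraction)
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Score one ligand-receptor channel
#'
#' The product of the mean normalized ligand expression over the sender
#' cells and the mean normalized receptor expression over the receiver
#' cells.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell tibble with `cell_id`, `cell_type`.
#' @param ligand,receptor Gene symbols.
#' @param sender,receiver Cell-type labels.
#' @return The scalar score.
#' @export
score_pair <- function(norm, cells, ligand, receptor, sender, receiver) {
  cells <- assert_aligned(norm, tibble::as_tibble(cells))
  s_idx <- which(cells$cell_type == sender)
  r_idx <- which(cells$cell_type == receiver)
  if (length(s_idx) == 0 || length(r_idx) == 0) {
    stop_mn("sender or receiver cell type has no cells", "mn_bad_input")
  }
  mean(norm[ligand, s_idx]) * mean(norm[receptor, r_idx])
}

#' Permutation test for ligand-receptor interaction scores
#'
#' For each permutation round, cell-type identities are shuffled globally
#' (one shuffle shared by every triple of the round, preserving type
#' counts), and each admissible triple is rescored.  The empirical p-value
#' uses the add-one convention `p = (1 + #\{null >= observed\}) / (1 + n_perm)`
#' with ties counting against significance.  With `exhaustive = TRUE`, all
#' distinct arrangements of the label multiset are enumerated instead of
#' sampled (small inputs only) and `n_perm` becomes the number of
#' arrangements.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell tibble with `cell_id`, `cell_type`.
#' @param triples Admissible triples from [screen_pairs()].
#' @param n_perm Number of permutation rounds (default 1000).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all distinct label arrangements.
#' @return A `mn_interactions` tibble: the triples with `score`, `p_val`,
#'   `n_perm`, plus the screening fractions.
#' @export
lr_permutation_test <- function(norm, cells, triples, n_perm = 1000L, seed = 1L,
                                exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop_mn("n_perm must be >= 1", "mn_bad_input")
  cells <- assert_aligned(norm, tibble::as_tibble(cells))
  labels <- cells$cell_type
  triples <- tibble::as_tibble(triples)
  if (nrow(triples) == 0) stop_mn("no admissible triples to test", "mn_bad_input")
  genes <- unique(c(triples$ligand, triples$receptor))
  sub <- as.matrix(norm[genes, , drop = FALSE])
  types <- sort(unique(labels))

  score_with <- function(lab) {
    mean_ <- vapply(types, function(tp) rowMeans(sub[, lab == tp, drop = FALSE]),
                    numeric(length(genes)))
    mean_ <- matrix(mean_, nrow = length(genes), dimnames = list(genes, types))
    mean_[cbind(triples$ligand, triples$sender)] *
      mean_[cbind(triples$receptor, triples$receiver)]
  }
  observed <- score_with(labels)

  perm_labels <- if (exhaustive) {
    multiset_permutations(labels)
  } else {
    withr::with_seed(seed, replicate(n_perm, sample(labels), simplify = FALSE))
  }
  n_used <- length(perm_labels)
  exceed <- numeric(nrow(triples))
  for (lab in perm_labels) {
    # type counts are preserved by a global label shuffle
    stopifnot(identical(as.vector(table(lab)), as.vector(table(labels))))
    exceed <- exceed + (score_with(lab) >= observed)
  }
  out <- triples |>
    dplyr::mutate(score = observed,
                  p_val = (1 + exceed) / (1 + n_used),
                  n_perm = n_used)
  attr(out, "p_convention") <- "add-one; ties count against significance"
  class(out) <- c("mn_interactions", class(out))
  out
}

#' Flag ligands exclusively expressed in a focal cell type
#'
#' A ligand is flagged exclusive when its signed marker Z for the focal
#' type exceeds `z_cutoff`.  Ligands absent from the marker table are
#' flagged `FALSE` and recorded.
#'
#' @param marker_results Tibble from [wilcoxon_markers()] for the focal type.
#' @param ligands Character vector of ligand symbols.
#' @param z_cutoff Signed-Z threshold (default 3).
#' @return A tibble (`ligand`, `z`, `exclusive`).
#' @export
flag_exclusive_ligands <- function(marker_results, ligands, z_cutoff = 3) {
  ligands <- unique(as.character(ligands))
  idx <- match(ligands, marker_results$gene)
  missing <- ligands[is.na(idx)]
  if (length(missing)) {
    rlang::inform(sprintf("%d ligands absent from the marker table flagged non-exclusive",
                          length(missing)))
  }
  z <- marker_results$z[idx]
  tibble::tibble(ligand = ligands, z = z,
                 exclusive = !is.na(z) & z > z_cutoff)
}
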