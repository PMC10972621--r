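#' Moving-average copy-number profile from expression
#'
#' A simplified expression-based CNV inference: every gene is centered by
#' its mean over the reference cells and clipped at `clip_sd` reference
#' standard deviations (per gene, floored at the median positive reference
#' SD so a constant reference gene cannot pin the profile to zero); the
#' centered values are smoothed with a moving average of `window` genes
#' along each chromosome in coordinate order (symmetrically shortened at
#' chromosome ends, never spanning two chromosomes); finally each cell's
#' profile is median-centered.  Immune or otherwise confidently non-malignant
#' cells are the natural reference.
#'
#' @param norm Normalized genes x cells matrix (log scale).
#' @param genes Gene tibble with `symbol`, `chromosome`, `rank` (or `start`).
#' @param reference_cells Character vector of reference cell ids.
#' @param window Odd moving-average length in genes (default 101).
#' @param clip_sd Clip bound in reference SD units (default 3).
#' @return A `mn_cnv` object: `profile` (smoothed genes x cells matrix in
#'   chromosome order), `windows` (tibble `symbol`, `chromosome`, `rank`,
#'   window bounds), `reference_cells`, `window`, `clip_sd`.
#' @export
infer_cnv <- function(norm, genes, reference_cells, window = 101L, clip_sd = 3) {
  if (length(reference_cells) == 0) stop_mn("reference cell list is empty", "mn_bad_input")
  if (window < 1 || window %% 2 == 0) stop_mn("window must be a positive odd integer", "mn_bad_input")
  genes <- tibble::as_tibble(genes)
  if (!"rank" %in% names(genes)) {
    genes <- genes |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::mutate(rank = rank(.data$start, ties.method = "first")) |>
      dplyr::ungroup()
  }
  genes <- genes[genes$symbol %in% rownames(norm), , drop = FALSE]
  sizes <- table(genes$chromosome)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    rlang::warn(sprintf("chromosomes with fewer than 3 genes excluded: %s",
                        paste(small, collapse = ", ")))
    genes <- genes[!genes$chromosome %in% small, , drop = FALSE]
  }
  if (nrow(genes) == 0) stop_mn("no usable genes for CNV inference", "mn_bad_input")
  chrom_order <- unique(genes$chromosome)
  genes <- genes[order(match(genes$chromosome, chrom_order), genes$rank), , drop = FALSE]
  missing_ref <- setdiff(reference_cells, colnames(norm))
  if (length(missing_ref)) {
    stop_mn(sprintf("%d reference cells absent from the matrix", length(missing_ref)),
            "mn_bad_input")
  }
  X <- as.matrix(norm[genes$symbol, , drop = FALSE])
  ref <- X[, reference_cells, drop = FALSE]
  mu <- rowMeans(ref)
  s <- apply(ref, 1, stats::sd)
  s[!is.finite(s)] <- 0  # a single reference cell has no spread
  floor_s <- stats::median(s[s > 0])
  if (!is.finite(floor_s) || floor_s <= 0) floor_s <- 0.1
  s <- pmax(s, floor_s)
  C <- X - mu
  bound <- clip_sd * s
  C <- pmin(pmax(C, -bound), bound)

  h <- (window - 1L) %/% 2L
  smooth <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  win_start <- win_end <- integer(nrow(C))
  for (ch in chrom_order) {
    idx <- which(genes$chromosome == ch)
    n <- length(idx)
    cs <- apply(rbind(0, C[idx, , drop = FALSE]), 2, cumsum)  # (n+1) x cells
    k <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
    lo <- seq_len(n) - k
    hi <- seq_len(n) + k
    smooth[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (2 * k + 1)
    win_start[idx] <- lo
    win_end[idx] <- hi
  }
  med <- apply(smooth, 2, stats::median)
  smooth <- sweep(smooth, 2, med, "-")
  structure(list(
    profile = smooth,
    windows = tibble::tibble(symbol = genes$symbol, chromosome = genes$chromosome,
                             rank = genes$rank, window_start = win_start,
                             window_end = win_end),
    reference_cells = reference_cells, window = window, clip_sd = clip_sd
  ), class = "mn_cnv")
}

#' Call a planted or candidate segment from a CNV profile
#'
#' For each cell, averages the smoothed profile over the segment's genes and
#' compares it with the distribution of the same average across the
#' reference cells: a gain is called when the cell exceeds the reference
#' mean by `sd_mult` reference SDs (a loss when it falls below by the same
#' margin).
#'
#' @param cnv A `mn_cnv` object from [infer_cnv()].
#' @param segment_genes Symbols of the genes inside the segment.
#' @param direction `"gain"` or `"loss"`.
#' @param sd_mult Detection margin in reference SD units (default 2).
#' @return A tibble (`cell_id`, `segment_mean`, `detected`).
#' @export
detect_cnv_segment <- function(cnv, segment_genes, direction = c("gain", "loss"),
                               sd_mult = 2) {
  direction <- match.arg(direction)
  rows <- intersect(segment_genes, rownames(cnv$profile))
  if (length(rows) == 0) stop_mn("no segment gene is present in the profile", "mn_bad_input")
  seg_mean <- colMeans(cnv$profile[rows, , drop = FALSE])
  ref <- seg_mean[cnv$reference_cells]
  thr_hi <- mean(ref) + sd_mult * stats::sd(ref)
  thr_lo <- mean(ref) - sd_mult * stats::sd(ref)
  tibble::tibble(
    cell_id = names(seg_mean),
    segment_mean = unname(seg_mean),
    detected = if (direction == "gain") seg_mean > thr_hi else seg_mean < thr_lo
  )
}
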