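# ggplot2 views of the main result types

#' Box plot of per-sample cell-type proportions by condition
#'
#' @param x A `mn_composition` object.
#' @return A ggplot.
#' @export
plot_composition <- function(x) {
  stopifnot(inherits(x, "mn_composition"))
  ggplot2::ggplot(x$proportions,
                  ggplot2::aes(x = .data$cell_type, y = .data$proportion,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(jitter.width = 0.12,
                                                                 dodge.width = 0.8),
                        size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "proportion of sample") +
    ggplot2::theme_classic()
}

#' Kaplan-Meier step curves
#'
#' @param object A `mn_km` curve table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mn_km
#' @export
autoplot.mn_km <- function(object, ...) {
  start <- object |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(time = 0, survival = 1, .groups = "drop")
  d <- dplyr::bind_rows(start,
                        dplyr::select(tibble::as_tibble(object),
                                      "stratum", "time", "survival"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_classic()
}

#' Dot plot of ligand-receptor interaction results
#'
#' Dot size shows the ligand expression fraction in the sender type, colour
#' the interaction score; non-significant channels are dropped.
#'
#' @param x A `mn_interactions` table.
#' @param alpha Significance threshold on the permutation p (default 0.05).
#' @return A ggplot.
#' @export
plot_lr_dotplot <- function(x, alpha = 0.05) {
  d <- tibble::as_tibble(x) |>
    dplyr::filter(.data$p_val <= alpha) |>
    dplyr::mutate(channel = paste(.data$ligand, .data$receptor, sep = " → "),
                  direction = paste(.data$sender, .data$receiver, sep = " → "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direction, y = .data$channel,
                                  size = .data$ligand_frac, colour = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "sender → receiver", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap-style tile view of a CNV profile
#'
#' @param x A `mn_cnv` object.
#' @param cells Optional cell ids to display (default: all, reference last).
#' @return A ggplot.
#' @export
plot_cnv_profile <- function(x, cells = NULL) {
  d <- tidy(x)
  if (!is.null(cells)) d <- d |> dplyr::filter(.data$cell_id %in% cells)
  ord <- x$windows$symbol
  d <- d |> dplyr::mutate(pos = match(.data$symbol, ord))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$cell_id,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "genes in chromosome order", y = NULL, fill = "CNV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
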