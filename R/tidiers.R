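# broom-style tidiers for fitted result objects

#' @method tidy mn_composition
#' @export
tidy.mn_composition <- function(x, ...) x$tests

#' @method glance mn_composition
#' @export
glance.mn_composition <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$samples), n_cell_types = nrow(x$tests),
                 group_a = x$groups[1], group_b = x$groups[2],
                 min_p = min(x$tests$p_val))
}

#' @method tidy mn_de
#' @export
tidy.mn_de <- function(x, ...) x$results

#' @method glance mn_de
#' @export
glance.mn_de <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$results), n_tested = sum(x$results$tested),
                 n_samples = nrow(x$samples),
                 n_signif_05 = sum(x$results$p_adj < 0.05, na.rm = TRUE))
}

#' @method tidy mn_logrank
#' @export
tidy.mn_logrank <- function(x, ...) x$table

#' @method glance mn_logrank
#' @export
glance.mn_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_val = x$p_val,
                 observed_a = x$observed_a, expected_a = x$expected_a)
}

#' @method tidy mn_signature_derivation
#' @export
tidy.mn_signature_derivation <- function(x, ...) x$provenance

#' @method glance mn_signature_derivation
#' @export
glance.mn_signature_derivation <- function(x, ...) {
  tibble::tibble(z_cutoff = x$z_cutoff, n_genes = length(x$signature$genes),
                 n_pass_vs_primary = sum(x$provenance$pass_vs_primary),
                 n_pass_vs_nonmalignant = sum(x$provenance$pass_vs_nonmalignant))
}

#' @method tidy mn_cnv
#' @export
tidy.mn_cnv <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$profile), rownames = "symbol") |>
    tidyr::pivot_longer(-"symbol", names_to = "cell_id", values_to = "value") |>
    dplyr::left_join(x$windows, by = "symbol")
}
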