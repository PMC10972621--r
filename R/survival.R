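#' Kaplan-Meier product-limit estimate
#'
#' Computed from the definition: at each distinct event time `t_i` with
#' `d_i` events among `n_i` at risk, the survival estimate multiplies by
#' `1 - d_i / n_i`.  Records censored at a time leave the risk set after
#' events at that time (the standard tie convention).
#'
#' @param surv Tibble with `time` (non-negative), `event` (0 censored /
#'   1 event) and optionally `stratum`.
#' @param stratum Optional stratum label to subset to; with `NULL` and a
#'   `stratum` column present, one curve per stratum is returned.
#' @return A `mn_km` tibble: `stratum`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` at each distinct observed time.
#' @export
km_estimate <- function(surv, stratum = NULL) {
  surv <- tibble::as_tibble(surv)
  if (any(surv$time < 0)) stop_mn("negative follow-up times", "mn_bad_input")
  if (!all(surv$event %in% c(0, 1))) stop_mn("event indicator must be 0/1", "mn_bad_input")
  if (!is.null(stratum)) {
    surv <- surv[surv$stratum == stratum, , drop = FALSE]
    if (nrow(surv) == 0) stop_mn(sprintf("stratum '%s' is empty", stratum), "mn_bad_input")
  }
  strata <- if ("stratum" %in% names(surv)) split(surv, surv$stratum) else list(all = surv)
  out <- purrr::imap(strata, function(d, nm) {
    times <- sort(unique(d$time))
    n_risk <- vapply(times, function(t) sum(d$time >= t), numeric(1))
    n_event <- vapply(times, function(t) sum(d$time == t & d$event == 1), numeric(1))
    n_censor <- vapply(times, function(t) sum(d$time == t & d$event == 0), numeric(1))
    s <- cumprod(1 - n_event / n_risk)
    tibble::tibble(stratum = nm, time = times, n_risk = n_risk,
                   n_event = n_event, n_censor = n_censor, survival = s)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("mn_km", class(res))
  res
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation given the pooled risk set; the
#' statistic `(sum(O - E))^2 / sum(V)` is referred to a chi-square with one
#' degree of freedom.  Symmetric in the two strata.
#'
#' @param surv Tibble with `time`, `event`, `stratum`.
#' @param stratum_a,stratum_b The two stratum labels to compare.
#' @return A `mn_logrank` object: `statistic`, `p_val`, `df`, the per-time
#'   `table` (`time`, `n_risk_a`, `n_risk`, `n_event_a`, `n_event`,
#'   `expected_a`, `variance`), and observed/expected totals.
#' @export
logrank_test <- function(surv, stratum_a, stratum_b) {
  surv <- tibble::as_tibble(surv)
  d <- surv[surv$stratum %in% c(stratum_a, stratum_b), , drop = FALSE]
  if (!any(d$stratum == stratum_a) || !any(d$stratum == stratum_b)) {
    stop_mn("both strata must be non-empty", "mn_bad_input")
  }
  if (any(d$time < 0)) stop_mn("negative follow-up times", "mn_bad_input")
  if (sum(d$event) == 0) {
    stop_mn("no events in either stratum: log-rank statistic undefined", "mn_no_events")
  }
  ev_times <- sort(unique(d$time[d$event == 1]))
  tab <- purrr::map_dfr(ev_times, function(t) {
    at_risk <- d$time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & d$stratum == stratum_a)
    d_tot <- sum(d$time == t & d$event == 1)
    d_a <- sum(d$time == t & d$event == 1 & d$stratum == stratum_a)
    e_a <- d_tot * n_a / n
    v <- if (n > 1) d_tot * (n_a / n) * (1 - n_a / n) * (n - d_tot) / (n - 1) else 0
    tibble::tibble(time = t, n_risk_a = n_a, n_risk = n, n_event_a = d_a,
                   n_event = d_tot, expected_a = e_a, variance = v)
  })
  o_minus_e <- sum(tab$n_event_a - tab$expected_a)
  v_sum <- sum(tab$variance)
  if (v_sum <= 0) stop_mn("zero log-rank variance (degenerate risk sets)", "mn_no_events")
  stat <- o_minus_e^2 / v_sum
  structure(list(statistic = stat,
                 p_val = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L,
                 observed_a = sum(tab$n_event_a), expected_a = sum(tab$expected_a),
                 strata = c(stratum_a, stratum_b), table = tab),
            class = "mn_logrank")
}

#' @export
print.mn_logrank <- function(x, ...) {
  cat(sprintf("<mn_logrank> %s vs %s: chi-square = %.4g on 1 df, p = %.4g\n",
              x$strata[1], x$strata[2], x$statistic, x$p_val))
  invisible(x)
}
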