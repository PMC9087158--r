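# Per-time-step monitors and run summaries.
#
# The eight headline performance variables are: workers in system, mean
# satisfaction, mean trust, cumulative treatment cost, cumulative total
# cost, cumulative wage replacement cost, mean claim duration at exit, and
# mean worker health. The snapshot adds stage counts, the remaining cost
# categories, RTW/dispute/termination counters and the accepted/rejected
# trust split.

METRIC_COLS <- c(
  "t", "n_in_system",
  paste0("n_", c("gp", "emergency", "workplace", "lodgement",
                 "accepted_waiting", "treatment", "dispute", "rtw_pool")),
  "mean_health", "mean_trust", "mean_satisfaction",
  "mean_trust_accepted", "mean_trust_rejected",
  "cum_medical_cost", "cum_treatment_cost", "cum_wage_cost",
  "cum_occ_rehab_cost", "cum_advertising_cost", "cum_total_cost",
  "n_full_rtw", "n_partial_rtw", "n_failed_rtw", "n_disputes",
  "n_terminated", "mean_claim_duration_at_exit")

#' The eight headline outcome variables
#'
#' @return Character vector of the outcome column names compared across
#'   experimental conditions.
#' @export
outcome_variables <- function() {
  c("n_in_system", "mean_satisfaction", "mean_trust", "cum_treatment_cost",
    "cum_total_cost", "cum_wage_cost", "mean_claim_duration_at_exit",
    "mean_health")
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

snapshot_row <- function(s) {
  p <- s$pop
  live <- s$live_ids
  stg <- p$stage[live]
  tba <- trust_by_acceptance(s)
  c(t = s$t,
    n_in_system = length(live),
    n_gp = sum(stg == ST_GP), n_emergency = sum(stg == ST_ED),
    n_workplace = sum(stg == ST_WORKPLACE),
    n_lodgement = sum(stg == ST_LODGEMENT),
    n_accepted_waiting = sum(stg == ST_ACCEPTED),
    n_treatment = sum(stg == ST_TREATMENT),
    n_dispute = sum(stg == ST_DISPUTE),
    n_rtw_pool = sum(stg == ST_RTW_POOL),
    mean_health = mean_or_na(p$health[live]),
    mean_trust = mean_or_na(p$trust[live]),
    mean_satisfaction = mean_or_na(p$satisfaction[live]),
    mean_trust_accepted = tba[["accepted"]],
    mean_trust_rejected = tba[["rejected"]],
    cum_medical_cost = s$sys_medical / 100,
    cum_treatment_cost = s$sys_treatment / 100,
    cum_wage_cost = s$sys_wage / 100,
    cum_occ_rehab_cost = s$sys_occ_rehab / 100,
    cum_advertising_cost = s$sys_advertising / 100,
    cum_total_cost = total_cost_cents(s) / 100,
    n_full_rtw = s$n_full_rtw, n_partial_rtw = s$n_partial_rtw,
    n_failed_rtw = s$n_failed_rtw, n_disputes = s$n_disputes,
    n_terminated = s$n_terminated,
    mean_claim_duration_at_exit =
      if (s$n_dur > 0) s$sum_dur / s$n_dur else NA_real_)
}

#' Snapshot the per-step monitors
#'
#' A pure read of the system state: stage counts, population means of
#' health/trust/satisfaction (reported as `NA` over an empty system, never
#' zero), cumulative cost categories in dollars, cumulative RTW, dispute and
#' termination counts, and the mean claim duration over workers exited so
#' far.
#'
#' @param state a `worksim_state`.
#' @return A one-row data.frame with the columns documented in
#'   [timeseries_schema()].
#' @export
snapshot <- function(state) {
  as.data.frame(as.list(snapshot_row(state)))
}

#' Mean trust split by claim acceptance status
#'
#' Conditional means of trust over all workers ever seen (live and exited),
#' split by whether their claim is currently accepted or rejected; workers
#' with a pending claim contribute to neither. Means over empty groups are
#' `NA`.
#'
#' @param state a `worksim_state`.
#' @return Named numeric vector `c(accepted = , rejected = )`.
#' @export
trust_by_acceptance <- function(state) {
  s <- state
  p <- s$pop
  live <- s$live_ids
  acc <- live[p$accepted[live] == ACC_ACCEPTED]
  rej <- live[p$accepted[live] == ACC_REJECTED]
  acc_sum <- sum(p$trust[acc]) + s$ex_trust_acc_sum
  acc_n <- length(acc) + s$ex_trust_acc_n
  rej_sum <- sum(p$trust[rej]) + s$ex_trust_rej_sum
  rej_n <- length(rej) + s$ex_trust_rej_n
  c(accepted = if (acc_n > 0) acc_sum / acc_n else NA_real_,
    rejected = if (rej_n > 0) rej_sum / rej_n else NA_real_)
}

#' Mean claim duration at exit
#'
#' @param state a `worksim_state`.
#' @param include_terminated include workers whose benefits were terminated
#'   at the maximum claim duration (default `TRUE`); `FALSE` restricts to
#'   claims closed by return to work, for sensitivity analyses.
#' @return Mean duration in time-steps, `NA` if no claims have closed.
#' @export
mean_claim_duration <- function(state, include_terminated = TRUE) {
  s <- state
  if (include_terminated) {
    if (s$n_dur > 0) s$sum_dur / s$n_dur else NA_real_
  } else {
    n <- s$n_dur - s$n_dur_term
    if (n > 0) (s$sum_dur - s$sum_dur_term) / n else NA_real_
  }
}

#' Column schema of the monitor time-series
#'
#' @return Character vector of the wide-format CSV column names, in order.
#' @export
timeseries_schema <- function() METRIC_COLS

#' Write and read monitor time-series CSV files
#'
#' `write_timeseries()` writes the per-step monitors in wide form (one row
#' per time-step, columns per [timeseries_schema()]) and, optionally, tidy
#' form (one row per `t`/`metric`/`value` triple). Both round-trip
#' losslessly through `read_timeseries()`.
#'
#' @param series data.frame of snapshots (the `series` of a `worksim_run`).
#' @param path output CSV path (wide format).
#' @param tidy_path optional second path for the tidy long format.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, tidy_path = NULL) {
  if (!nrow(series)) stop("empty metrics series", call. = FALSE)
  stopifnot(identical(names(series), METRIC_COLS))
  utils::write.csv(series, path, row.names = FALSE)
  if (!is.null(tidy_path)) {
    long <- data.frame(
      t = rep(series$t, times = length(METRIC_COLS) - 1L),
      metric = rep(METRIC_COLS[-1], each = nrow(series)),
      value = unlist(series[METRIC_COLS[-1]], use.names = FALSE))
    utils::write.csv(long, tidy_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(names(out), METRIC_COLS))
  out
}
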