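# Treatment dynamics, wage replacement and the return-to-work pathways.

#' One treatment step of health improvement
#'
#' Treatment closes a fixed fraction (default 5%) of the gap between current
#' health and the 100-point maximum per time-step, scaled by the worker's
#' responsiveness multiplier, plus a symmetric random perturbation of up to
#' one health unit:
#' `health' = clamp(health + rate * (100 - health) * responsiveness + eps)`.
#' Recovery is therefore fast early in a claim and slows near full health.
#'
#' @param health current health in `[0, 100]` (vectorized).
#' @param responsiveness multiplier in `[-1, 1]` (recycled).
#' @param levers a `worksim_levers` list (`treatment_gain_rate`,
#'   `treatment_noise`).
#' @param eps optional noise values to use instead of fresh draws; pass `0`
#'   to disable noise (deterministic trajectory).
#' @return Updated health vector, clamped to `[0, 100]`.
#' @examples
#' treat_step(0, 1, eps = 0)      # 5: five percent of the 100-point gap
#' treat_step(50, 0.8, eps = 0)   # 52
#' @export
treat_step <- function(health, responsiveness, levers = default_levers(),
                       eps = NULL) {
  n <- length(health)
  if (is.null(eps)) eps <- q_noise(stats::runif(n), levers$treatment_noise)
  clamp100(health + levers$treatment_gain_rate * (100 - health) *
             responsiveness + eps)
}

#' Closed-form noise-free treatment trajectory
#'
#' With the random perturbation disabled, health after `t` treated steps is
#' `100 - (100 - h0) * (1 - rate * r)^t`. Used as the analytic oracle for the
#' simulated trajectory.
#'
#' @param h0 starting health.
#' @param responsiveness multiplier in `[-1, 1]`.
#' @param t number of treated steps (vectorized).
#' @param rate per-step fraction of the health gap closed (default 0.05).
#' @return Health after `t` steps (unclamped analytic value).
#' @export
treatment_trajectory <- function(h0, responsiveness, t, rate = 0.05) {
  100 - (100 - h0) * (1 - rate * responsiveness)^t
}

#' Sample medical cost draws
#'
#' Treatment-service and GP-visit costs are normal with the configured mean
#' and sd (defaults $100, sd $20), truncated at zero and rounded to cents.
#' Emergency presentations cost a fixed `ed_cost` (default $1000).
#'
#' @param n number of draws.
#' @param levers a `worksim_levers` list.
#' @param u optional uniforms to transform (scripted scenarios).
#' @return Numeric vector of costs in dollars (two decimals).
#' @export
sample_treatment_cost <- function(n, levers = default_levers(), u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  round(q_cost(u, levers$treatment_cost_mean, levers$treatment_cost_sd), 2)
}

#' @rdname sample_treatment_cost
#' @export
sample_gp_cost <- function(n, levers = default_levers(), u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  round(q_cost(u, levers$gp_cost_mean, levers$gp_cost_sd), 2)
}

#' Per-step wage replacement cost
#'
#' Workers with accepted claims receive income support at
#' `wage_replacement_fraction` (default 80%) of salary, converted to a
#' per-step amount via `steps_per_year`. During partial return-to-work the
#' entitlement is reduced by the proportion of health the worker has
#' achieved: a worker at 75% fitness costs 25% of the 80% entitlement.
#'
#' @param salary annual salary (vectorized).
#' @param levers a `worksim_levers` list.
#' @param fitness_credit fraction of capacity recovered, in `[0, 1]`; 0 while
#'   fully off work, `health/100` during partial return-to-work.
#' @return Per-time-step wage cost in dollars (two decimals).
#' @examples
#' accrue_wage_cost(55000)                          # 0.80 * 55000 / 50
#' accrue_wage_cost(55000, fitness_credit = 0.75)   # quarter of the above
#' @export
accrue_wage_cost <- function(salary, levers = default_levers(),
                             fitness_credit = 0) {
  if (any(fitness_credit < 0 | fitness_credit > 1)) {
    stop("fitness_credit must be in [0, 1]", call. = FALSE)
  }
  round((1 - fitness_credit) * levers$wage_replacement_fraction *
          salary / levers$steps_per_year, 2)
}

#' Return-to-work gate
#'
#' A worker in treatment moves to the RTW pool (full return) on reaching the
#' claim threshold. Under the `encourage` policy, workers at or above the
#' early-RTW health floor but below the threshold are routed to an employer
#' return attempt; otherwise they stay in treatment.
#'
#' @param health current health (vectorized).
#' @param levers a `worksim_levers` list (`claim_threshold`, `rtw_policy`,
#'   `early_rtw_health_floor`).
#' @return Character vector in
#'   `{"to_rtw_pool", "to_employer_attempt", "stay_in_treatment"}`.
#' @examples
#' rtw_gate(96, default_levers())   # "to_rtw_pool"
#' @export
rtw_gate <- function(health, levers = default_levers()) {
  out <- rep("stay_in_treatment", length(health))
  out[health >= levers$claim_threshold] <- "to_rtw_pool"
  if (levers$rtw_policy == "encourage") {
    out[health < levers$claim_threshold &
          health >= levers$early_rtw_health_floor] <- "to_employer_attempt"
  }
  out
}

#' Employer readiness after advertising
#'
#' Advertising spend raises employer readiness to accommodate a returning
#' worker through a saturating gain
#' `g(s) = gain_max * s / (s + half_sat)`, clamped to `[0, 100]`.
#'
#' @param base_readiness readiness points before advertising (vectorized).
#' @param levers a `worksim_levers` list (`advertising_spend`,
#'   `advertising_readiness_gain`, `advertising_half_sat`).
#' @return Readiness in `[0, 100]`.
#' @export
readiness_with_advertising <- function(base_readiness,
                                       levers = default_levers()) {
  s <- levers$advertising_spend
  gain <- levers$advertising_readiness_gain * s / (s + levers$advertising_half_sat)
  if (s == 0) gain <- 0
  clamp100(base_readiness + gain)
}

#' Outcome of an employer return-to-work attempt
#'
#' The worker's health shortfall against the claim threshold is compared with
#' the employer's readiness: readiness at least the shortfall yields a
#' partial return; otherwise occupational rehabilitation (when enabled and
#' not capacity-exhausted, decided by the caller) can bridge the gap, and
#' failing that the attempt is a failed RTW and the worker returns to
#' treatment.
#'
#' @param health worker health (vectorized).
#' @param readiness employer readiness after advertising (recycled).
#' @param levers a `worksim_levers` list.
#' @param occ_rehab_available logical (recycled): occupational rehabilitation
#'   support can be applied to this attempt.
#' @return Character vector in `{"partial_rtw", "partial_rtw_occ_rehab",
#'   "failed_rtw"}`.
#' @examples
#' attempt_employer_rtw(80, 20, default_levers())  # shortfall 15 <= 20
#' @export
attempt_employer_rtw <- function(health, readiness,
                                 levers = default_levers(),
                                 occ_rehab_available = FALSE) {
  shortfall <- levers$claim_threshold - health
  out <- rep("failed_rtw", length(shortfall))
  ok <- readiness >= shortfall
  out[ok] <- "partial_rtw"
  bridge <- !ok & rep_len(occ_rehab_available, length(shortfall))
  out[bridge] <- "partial_rtw_occ_rehab"
  out
}

#' Benefit termination check
#'
#' A claim is terminated once its duration strictly surpasses the maximum
#' claim duration; a duration exactly at the limit is not terminated.
#'
#' @param claim_active_since time-step of claim acceptance (vectorized;
#'   `NA` = no accepted claim, never terminated).
#' @param t current time-step.
#' @param levers a `worksim_levers` list (`max_claim_duration`).
#' @return Logical vector: claim terminated this step.
#' @export
check_termination <- function(claim_active_since, t,
                              levers = default_levers()) {
  !is.na(claim_active_since) &
    (t - claim_active_since) > levers$max_claim_duration
}
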