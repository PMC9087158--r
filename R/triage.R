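# Triage referral decisions and adjudication draws — the same decision rules
# the engine applies, exposed as vectorized functions for measurement.

#' GP referral decision
#'
#' A GP compares assessed health with the claim threshold: below-threshold
#' workers are referred to claim lodgement, the rest back to the workplace.
#' The assessment matches the true comparison with probability `gp_accuracy`;
#' otherwise the opposite referral is made (the misdiagnosis mechanism).
#'
#' @param health worker health (vectorized).
#' @param levers a `worksim_levers` list.
#' @param u optional uniforms (length of `health`) deciding assessment
#'   correctness; drawn fresh when `NULL`.
#' @return Character vector in `{"to_lodgement", "to_workplace"}`.
#' @examples
#' gp_referral(40, default_levers(gp_accuracy = 1))   # "to_lodgement"
#' @export
gp_referral <- function(health, levers = default_levers(), u = NULL) {
  if (is.null(u)) u <- stats::runif(length(health))
  truth_lodge <- health < levers$claim_threshold
  correct <- u < levers$gp_accuracy
  to_lodge <- (correct & truth_lodge) | (!correct & !truth_lodge)
  ifelse(to_lodge, "to_lodgement", "to_workplace")
}

#' Emergency-department referral decision
#'
#' The emergency assessment applies the same threshold comparison as the GP
#' but without a misdiagnosis rate.
#'
#' @inheritParams gp_referral
#' @return Character vector in `{"to_lodgement", "to_workplace"}`.
#' @export
ed_referral <- function(health, levers = default_levers()) {
  ifelse(health < levers$claim_threshold, "to_lodgement", "to_workplace")
}

accept_rates <- function(levers) {
  c(levers$accept_rate_acute, levers$accept_rate_chronic,
    levers$accept_rate_mental)
}

#' Adjudicate injury claims
#'
#' Accept each claim with the injury-type-specific base rate (defaults 0.90
#' acute physical, 0.60 chronic physical, 0.40 mental health).
#'
#' @param injury_type character vector of injury types (see
#'   `c("acute_physical", "chronic_physical", "mental_health")`).
#' @param levers a `worksim_levers` list.
#' @param u optional uniforms deciding each outcome.
#' @return Logical vector: claim accepted.
#' @examples
#' set.seed(1)
#' mean(adjudicate_claims(rep("acute_physical", 1000)))
#' @export
adjudicate_claims <- function(injury_type, levers = default_levers(),
                              u = NULL) {
  idx <- match(injury_type, INJURY_TYPES)
  if (anyNA(idx)) stop("unknown injury type", call. = FALSE)
  if (is.null(u)) u <- stats::runif(length(idx))
  u < accept_rates(levers)[idx]
}

#' Resolve disputes
#'
#' Each dispute is upheld for the worker with probability
#' `dispute_success_rate`.
#'
#' @param n number of disputes.
#' @param levers a `worksim_levers` list.
#' @param u optional uniforms.
#' @return Logical vector: dispute upheld for the worker.
#' @export
resolve_disputes <- function(n, levers = default_levers(), u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  u < levers$dispute_success_rate
}
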