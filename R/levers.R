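#' Default policy levers
#'
#' Construct the full set of policy and claims-management levers of the
#' simulated compensation scheme, with every field at its documented default.
#' Levers cover the claim-eligibility threshold, adjudication acceptance rates
#' by injury type, triage split and medical costs, administrative and
#' treatment capacities, treatment economics, wage replacement,
#' return-to-work (RTW) policy, occupational rehabilitation, advertising,
#' disputes, benefit termination, arrivals and entrant attribute
#' distributions.
#'
#' @param ... named overrides for any lever field. Unknown names are an error.
#'
#' @return A named list of class `worksim_levers`.
#'
#' @details Key defaults: injury claims are eligible below a health score of
#' 95/100; acute physical, chronic physical and mental-health claims are
#' accepted at base rates 0.90, 0.60 and 0.40; entrants split 50/50 between
#' GP (mean cost $100) and emergency ($1000) presentation; treatment services
#' cost $100 (sd $20) and close 5% of the remaining health gap per step,
#' scaled by individual responsiveness; wage replacement is 80% of salary,
#' reduced pro-rata during partial RTW; occupational rehabilitation costs the
#' scheme $10,000 per supported worker; workers arrive at 10 per time-step
#' and expect claims processed within about 35 steps.
#'
#' @examples
#' lv <- default_levers()
#' lv$accept_rate_acute
#' lv2 <- default_levers(treatment_denial_rate = 0.2, rtw_policy = "encourage")
#' @export
default_levers <- function(...) {
  lv <- list(
    # eligibility and adjudication
    claim_threshold        = 95,
    accept_rate_acute      = 0.90,
    accept_rate_chronic    = 0.60,
    accept_rate_mental     = 0.40,
    # triage
    p_gp_first             = 0.5,
    gp_cost_mean           = 100,
    gp_cost_sd             = 20,
    ed_cost                = 1000,
    gp_accuracy            = 0.9,
    # capacities
    claims_processing_capacity = 12,
    treatment_capacity     = 1000,
    capacity_variation_enabled = FALSE,
    # treatment economics and dynamics
    treatment_cost_mean    = 100,
    treatment_cost_sd      = 20,
    treatment_gain_rate    = 0.05,
    treatment_noise        = 1,
    treatment_denial_rate  = 0.05,
    waitlist_drift_mean    = 0.01,
    waitlist_drift_sd      = 0.1,
    # wage replacement
    wage_replacement_fraction = 0.80,
    steps_per_year         = 50,
    # return to work
    rtw_policy             = "neutral",
    early_rtw_health_floor = 70,
    occ_rehab_enabled      = FALSE,
    occ_rehab_cost         = 10000,
    occ_rehab_capacity     = 10,
    employer_readiness_max = 30,
    # advertising
    advertising_spend      = 0,
    advertising_readiness_gain = 50,
    advertising_half_sat   = 1000,
    # disputes
    dispute_success_rate   = 0.5,
    dispute_duration       = 5,
    dispute_fight_exp      = 1,
    dispute_trust_exp      = 1,
    dispute_max_repeats    = Inf,
    # termination
    max_claim_duration     = 1000,
    # arrivals
    arrival_rate           = 10,
    arrival_variation_enabled = FALSE,
    # worker expectations and entry attribute distributions
    expectation_wait_mean  = 35,
    expectation_wait_sd    = 10,
    injury_mix             = c(acute_physical = 1 / 3,
                               chronic_physical = 1 / 3,
                               mental_health = 1 / 3),
    salary_mean            = 55000,
    salary_sd              = 10000,
    entry_health_min       = 20,
    entry_trust_min        = 50,
    entry_trust_max        = 100,
    entry_satisfaction_min = 50,
    entry_satisfaction_max = 100,
    entry_fight_min        = 0,
    entry_fight_max        = 100,
    responsiveness_mean    = 0.8,
    responsiveness_sd      = 0.2,
    memory_span            = 300,
    # psychological event deltas (trust, satisfaction); directions are the
    # model definition, magnitudes are levers
    psych_deltas           = default_psych_deltas(),
    # optional toggles, minimal semantics
    mistrust_contagion_enabled = FALSE,
    mistrust_contagion_prob = 0.01,
    mass_incident_step     = 0,
    mass_incident_size     = 0
  )
  class(lv) <- "worksim_levers"
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(lv))
    if (length(bad)) {
      stop("unknown lever field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    lv[names(overrides)] <- overrides
  }
  viol <- validate_levers(lv)
  if (length(viol)) {
    stop("invalid levers:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  lv
}

#' Default psychological event delta table
#'
#' Trust and satisfaction point changes applied when an event befalls a
#' worker, clamped into `[0, 100]` on application. Directions (adverse events
#' erode trust; a won dispute does not) define the mechanism; magnitudes are
#' configurable levers.
#'
#' @return A named list; each element is `c(trust = , satisfaction = )`.
#' @export
default_psych_deltas <- function() {
  list(
    claim_denied               = c(trust = -5, satisfaction = 0),
    treatment_denied           = c(trust = -5, satisfaction = 0),
    sent_back_from_workplace   = c(trust = -2, satisfaction = 0),
    wait_exceeded_expectation  = c(trust = -1, satisfaction = 0),
    in_dispute_step            = c(trust = -1, satisfaction = -1),
    dispute_lost               = c(trust = -5, satisfaction = -5),
    dispute_won                = c(trust = 2,  satisfaction = 0)
  )
}

#' Validate policy levers
#'
#' Check every lever invariant: probabilities in `[0, 1]`, capacities, costs
#' and durations non-negative, health thresholds in `[0, 100]`, the injury
#' mix summing to one. Violations are returned as data, not thrown.
#'
#' @param levers a `worksim_levers` list (see [default_levers()]).
#'
#' @return Character vector of violation descriptions, each naming the field,
#'   its value and the constraint; empty when all invariants hold.
#' @examples
#' validate_levers(default_levers())          # character(0)
#' lv <- default_levers(); lv$accept_rate_acute <- 1.5
#' validate_levers(lv)
#' @export
validate_levers <- function(levers) {
  v <- character(0)
  bad <- function(field, value, constraint) {
    sprintf("%s = %s violates: %s", field,
            paste(format(value), collapse = ", "), constraint)
  }
  chk_prob <- function(field) {
    x <- levers[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      v <<- c(v, bad(field, x, "must be a probability in [0, 1]"))
  }
  chk_nonneg <- function(field) {
    x <- levers[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      v <<- c(v, bad(field, x, "must be >= 0"))
  }
  chk_scale <- function(field) {
    x <- levers[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 100)
      v <<- c(v, bad(field, x, "must be in [0, 100]"))
  }
  for (f in c("accept_rate_acute", "accept_rate_chronic", "accept_rate_mental",
              "p_gp_first", "gp_accuracy", "treatment_denial_rate",
              "wage_replacement_fraction", "dispute_success_rate",
              "mistrust_contagion_prob")) chk_prob(f)
  for (f in c("gp_cost_mean", "gp_cost_sd", "ed_cost",
              "claims_processing_capacity", "treatment_capacity",
              "treatment_cost_mean", "treatment_cost_sd", "treatment_noise",
              "occ_rehab_cost", "occ_rehab_capacity", "employer_readiness_max",
              "advertising_spend", "advertising_readiness_gain",
              "dispute_duration", "dispute_max_repeats", "max_claim_duration",
              "arrival_rate", "expectation_wait_mean", "expectation_wait_sd",
              "salary_mean", "salary_sd", "steps_per_year", "memory_span",
              "mass_incident_size", "treatment_gain_rate")) chk_nonneg(f)
  for (f in c("claim_threshold", "early_rtw_health_floor",
              "entry_health_min")) chk_scale(f)
  mix <- levers$injury_mix
  if (!is.numeric(mix) || length(mix) != 3 || any(is.na(mix)) ||
      any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    v <- c(v, bad("injury_mix", mix,
                  "must be 3 non-negative probabilities summing to 1"))
  }
  if (!levers$rtw_policy %in% c("discourage", "neutral", "encourage")) {
    v <- c(v, bad("rtw_policy", levers$rtw_policy,
                  "must be one of discourage, neutral, encourage"))
  }
  if (!is.numeric(levers$steps_per_year) || levers$steps_per_year <= 0) {
    v <- c(v, bad("steps_per_year", levers$steps_per_year, "must be > 0"))
  }
  v
}

#' @export
print.worksim_levers <- function(x, ...) {
  cat("<worksim policy levers>\n")
  cat(sprintf("  claim threshold %g; accept rates acute/chronic/mental %g/%g/%g\n",
              x$claim_threshold, x$accept_rate_acute, x$accept_rate_chronic,
              x$accept_rate_mental))
  cat(sprintf("  capacities: claims %g/step, treatment %g; arrivals %g/step\n",
              x$claims_processing_capacity, x$treatment_capacity,
              x$arrival_rate))
  cat(sprintf("  rtw policy '%s' (floor %g); occ rehab %s; advertising $%g/step\n",
              x$rtw_policy, x$early_rtw_health_floor,
              if (isTRUE(x$occ_rehab_enabled)) "on" else "off",
              x$advertising_spend))
  invisible(x)
}

# fields allowed at the top level of a config file
config_top_fields <- c("n_steps", "seed", "output", "levers")

#' Load a simulation configuration from YAML
#'
#' Read a YAML file with optional top-level keys `n_steps`, `seed`, `output`
#' and a flat `levers:` mapping. Omitted fields take the documented defaults;
#' unknown keys (at either level) are an error, which catches misspelled
#' lever names. The resulting lever set is validated.
#'
#' @param path path to a YAML configuration file.
#'
#' @return A list of class `worksim_config` with elements `n_steps` (default
#'   2000), `seed` (default `NULL`), `output` (default `NULL`) and `levers`
#'   (a `worksim_levers` list).
#' @seealso [save_config()], [default_levers()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(raw), config_top_fields)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lv_over <- raw$levers
  if (is.null(lv_over)) lv_over <- list()
  if (!is.null(lv_over$injury_mix)) {
    lv_over$injury_mix <- unlist(lv_over$injury_mix)
  }
  if (!is.null(lv_over$psych_deltas)) {
    pd <- default_psych_deltas()
    for (ev in names(lv_over$psych_deltas)) {
      if (!ev %in% names(pd)) {
        stop("unknown psych event in config: ", ev, call. = FALSE)
      }
      d <- unlist(lv_over$psych_deltas[[ev]])
      pd[[ev]][names(d)] <- d
    }
    lv_over$psych_deltas <- pd
  }
  levers <- do.call(default_levers, lv_over)
  n_steps <- if (is.null(raw$n_steps)) 2000L else as.integer(raw$n_steps)
  if (is.na(n_steps) || n_steps < 1) {
    stop("n_steps must be an integer >= 1", call. = FALSE)
  }
  cfg <- list(n_steps = n_steps,
              seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
              output = raw$output,
              levers = levers)
  class(cfg) <- "worksim_config"
  cfg
}

#' Serialize a simulation configuration to YAML
#'
#' Writes a configuration so that [load_config()] of the result is
#' semantically identical to the original (round-trip property).
#'
#' @param config a `worksim_config` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  lv <- unclass(config$levers)
  lv$injury_mix <- as.list(lv$injury_mix)
  lv$psych_deltas <- lapply(lv$psych_deltas, as.list)
  out <- list(n_steps = config$n_steps, levers = lv)
  if (!is.null(config$seed)) out$seed <- config$seed
  if (!is.null(config$output)) out$output <- config$output
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.worksim_config <- function(x, ...) {
  cat(sprintf("<worksim config: %d steps, seed %s>\n", x$n_steps,
              if (is.null(x$seed)) "unset" else x$seed))
  print(x$levers)
  invisible(x)
}
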