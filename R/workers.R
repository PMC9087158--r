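# Injured-worker synthesis.
#
# Workers carry health, trust, satisfaction and fight-appetite on 100-point
# scales, a fixed treatment-responsiveness multiplier in [-1, 1], a
# positively skewed salary, an expectation of claim-processing time, an
# injury type, a bounded event memory and per-category cost ledgers.

INJURY_TYPES <- c("acute_physical", "chronic_physical", "mental_health")

WORKER_STAGES <- c("general_population", "gp", "emergency", "workplace_check",
                   "claim_lodgement", "claim_accepted_waiting", "treatment",
                   "dispute", "rtw_pool", "exited")

#' Sample annual salaries
#'
#' Salaries are drawn from a lognormal distribution re-parameterized so the
#' arithmetic mean and standard deviation match the configured population
#' values (defaults $55,000 and $10,000) — the simplest positively skewed
#' two-parameter family.
#'
#' @param n number of draws.
#' @param mean,sd target arithmetic mean and standard deviation.
#' @param u optional uniforms in `[0, 1]` (length `n`) to transform instead of
#'   drawing fresh ones; used by scripted scenarios.
#' @return Numeric vector of strictly positive salaries.
#' @examples
#' set.seed(1)
#' mean(sample_salary(1e4))
#' @export
sample_salary <- function(n, mean = 55000, sd = 10000, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  q_salary(u, mean, sd)
}

# number of uniforms consumed per spawned worker, in order:
# injury type, triage, health, trust, satisfaction, fight, responsiveness,
# salary, expectation
N_ATTR_DRAWS <- 9L

# Transform a matrix of uniforms (n x N_ATTR_DRAWS) into entrant attributes.
worker_attrs_from_unifs <- function(u, levers) {
  n <- nrow(u)
  mix <- cumsum(levers$injury_mix / sum(levers$injury_mix))
  injury <- findInterval(u[, 1], mix, left.open = TRUE) + 1L  # 1..3
  start_stage <- ifelse(u[, 2] < levers$p_gp_first, "gp", "emergency")
  hmin <- levers$entry_health_min
  health <- hmin + u[, 3] * (levers$claim_threshold - hmin)
  trust <- levers$entry_trust_min +
    u[, 4] * (levers$entry_trust_max - levers$entry_trust_min)
  satisfaction <- levers$entry_satisfaction_min +
    u[, 5] * (levers$entry_satisfaction_max - levers$entry_satisfaction_min)
  fight <- levers$entry_fight_min +
    u[, 6] * (levers$entry_fight_max - levers$entry_fight_min)
  responsiveness <- q_truncnorm(u[, 7], levers$responsiveness_mean,
                                levers$responsiveness_sd, -1, 1)
  salary <- q_salary(u[, 8], levers$salary_mean, levers$salary_sd)
  expectation <- pmax(1, round(stats::qnorm(
    u[, 9], levers$expectation_wait_mean, levers$expectation_wait_sd)))
  list(injury_type = INJURY_TYPES[injury], start_stage = start_stage,
       health = health, trust = trust, satisfaction = satisfaction,
       fight_appetite = fight, responsiveness = responsiveness,
       salary = salary, expectation_wait = expectation, n = n)
}

#' Synthesize a cohort of injured workers
#'
#' Draw `n` entrant workers from the configured attribute distributions:
#' injury type from the injury mix, initial presentation (GP vs emergency)
#' from the triage probability, entry health uniform on
#' `[entry_health_min, claim_threshold)`, trust and satisfaction uniform on
#' their entry ranges, fight appetite uniform, responsiveness truncated
#' normal on `[-1, 1]`, salary lognormal, and expected processing wait
#' normal (floored at 1 step).
#'
#' @param n number of workers.
#' @param levers a `worksim_levers` list.
#' @param rng optional `worksim_rng` source; `NULL` uses the global RNG.
#' @return A data.frame with one row per worker and columns `id`,
#'   `injury_type`, `start_stage`, `health`, `trust`, `satisfaction`,
#'   `fight_appetite`, `responsiveness`, `salary`, `expectation_wait`.
#' @examples
#' set.seed(7)
#' w <- sample_workers(5, default_levers())
#' @export
sample_workers <- function(n, levers = default_levers(), rng = NULL) {
  u <- matrix(rng_unif(rng, n * N_ATTR_DRAWS), nrow = n, ncol = N_ATTR_DRAWS,
              byrow = TRUE)
  a <- worker_attrs_from_unifs(u, levers)
  data.frame(id = seq_len(n), injury_type = a$injury_type,
             start_stage = a$start_stage, health = a$health, trust = a$trust,
             satisfaction = a$satisfaction, fight_appetite = a$fight_appetite,
             responsiveness = a$responsiveness, salary = a$salary,
             expectation_wait = a$expectation_wait,
             stringsAsFactors = FALSE)
}

# Counter-based attribute substream: the cohort spawned at time-step t draws
# its attribute uniforms from a dedicated stream seeded on (attr_seed, t),
# regardless of how much of the main stream other phases have consumed. Two
# conditions sharing attr_seed (and the same arrival schedule) therefore see
# identical entrant populations even after their pathways diverge.
worker_attr_unifs <- function(attr_seed, t, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((attr_seed + 2654435761 * t) %% 2147483647)
  matrix(stats::runif(n * N_ATTR_DRAWS), nrow = n, ncol = N_ATTR_DRAWS,
         byrow = TRUE)
}

#' Construct a single injured worker for tests and scenarios
#'
#' Build a worker with sensible fixed defaults (health 50, trust 75,
#' satisfaction 75, fight 50, responsiveness 0.8, salary $55,000) and apply
#' named overrides. Attribute invariants are enforced: unknown fields and
#' out-of-range values are errors.
#'
#' @param ... named overrides for worker fields (`health`, `trust`,
#'   `satisfaction`, `fight_appetite`, `responsiveness`, `salary`,
#'   `injury_type`, `expectation_wait`, `memory_span`, `stage`).
#' @return A list of class `injured_worker`, with a `memory` data.frame
#'   (columns `t`, `event`) and a zeroed `cost_ledger`.
#' @examples
#' w <- make_worker(health = 30, fight_appetite = 90)
#' @export
make_worker <- function(...) {
  w <- list(id = 1L, health = 50, trust = 75, satisfaction = 75,
            fight_appetite = 50, responsiveness = 0.8, salary = 55000,
            injury_type = "acute_physical", expectation_wait = 35,
            memory_span = 300, stage = "gp", accepted = "pending",
            claim_active_since = NA_integer_, failed_rtw_count = 0L,
            memory = data.frame(t = integer(0), event = character(0),
                                stringsAsFactors = FALSE),
            cost_ledger = c(gp = 0, emergency = 0, treatment = 0, wage = 0,
                            occ_rehab = 0))
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(w))
    if (length(bad)) {
      stop("unknown worker field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    w[names(overrides)] <- overrides
  }
  stopifnot_worker(w)
  class(w) <- "injured_worker"
  w
}

stopifnot_worker <- function(w) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  for (f in c("health", "trust", "satisfaction", "fight_appetite")) {
    chk(is.numeric(w[[f]]) && w[[f]] >= 0 && w[[f]] <= 100,
        paste0(f, " must be in [0, 100]"))
  }
  chk(w$responsiveness >= -1 && w$responsiveness <= 1,
      "responsiveness must be in [-1, 1]")
  chk(w$salary > 0, "salary must be > 0")
  chk(w$injury_type %in% INJURY_TYPES, "unknown injury_type")
  chk(w$stage %in% WORKER_STAGES, "unknown stage")
  chk(w$memory_span >= 0, "memory_span must be >= 0")
  chk(all(w$cost_ledger >= 0), "cost ledger entries must be >= 0")
  invisible(w)
}

#' @export
print.injured_worker <- function(x, ...) {
  cat(sprintf(
    "<injured worker #%d: %s, stage %s, health %.1f, trust %.1f, claim %s>\n",
    x$id, x$injury_type, x$stage, x$health, x$trust, x$accepted))
  invisible(x)
}
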