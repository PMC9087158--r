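# The per-time-step scheduler.
#
# SystemState is an environment holding the worker population as a
# data.table (one row per worker ever spawned; column updates go through
# data.table::set(), which writes in place and keeps a step cheap even with
# tens of thousands of rows), the lodgement queue, system cost ledgers (in
# integer cents, so conservation checks are exact), counters and the random
# source. advance() executes one time-step in a fixed phase order:
#   1 spawn cohort        2 GP/ED assessments     3 workplace re-checks
#   4 claim adjudication  5 dispute resolutions   6 treatment
#   7 RTW attempts        8 termination checks    9 wage accrual
#  10 psychology updates 11 metrics snapshot
# The intra-step order is part of the model definition (see the methods
# vignette); the random draws consumed by each phase are batched in a fixed
# order so that scripted random sources replay trajectories exactly.

# stage codes
ST_GP <- 1L; ST_ED <- 2L; ST_WORKPLACE <- 3L; ST_LODGEMENT <- 4L
ST_ACCEPTED <- 5L; ST_TREATMENT <- 6L; ST_DISPUTE <- 7L; ST_RTW_POOL <- 8L
ST_EXITED <- 9L
STAGE_NAMES <- c("gp", "emergency", "workplace_check", "claim_lodgement",
                 "claim_accepted_waiting", "treatment", "dispute", "rtw_pool",
                 "exited")

# accepted tri-state
ACC_PENDING <- 0L; ACC_ACCEPTED <- 1L; ACC_REJECTED <- 2L

# dispute kinds
DK_NONE <- 0L; DK_CLAIM <- 1L; DK_TREATMENT <- 2L

# exit reason codes
EXIT_RECOVERED_NO_CLAIM <- 1L; EXIT_DENIED_GAVE_UP <- 2L
EXIT_DISPUTE_LOST <- 3L; EXIT_FULL_RTW <- 4L; EXIT_TERMINATED <- 5L
EXIT_REASONS <- c("recovered_no_claim", "claim_denied_gave_up",
                  "dispute_lost", "full_rtw", "terminated")

empty_population <- function(n) {
  data.table::data.table(
    injury = integer(n), health = numeric(n), trust = numeric(n),
    satisfaction = numeric(n), fight = numeric(n), resp = numeric(n),
    salary = numeric(n), expect = numeric(n),
    stage = integer(n), accepted = integer(n),
    claim_start = rep(NA_integer_, n), queue_enter = rep(NA_integer_, n),
    dispute_enter = rep(NA_integer_, n), dispute_kind = integer(n),
    dispute_count = integer(n), failed_rtw = integer(n),
    led_gp = numeric(n), led_ed = numeric(n), led_treat = numeric(n),
    led_wage = numeric(n), transferred = logical(n),
    exit_reason = integer(n), claim_dur = rep(NA_real_, n))
}

#' Create an empty system state
#'
#' @param levers a `worksim_levers` list.
#' @param rng optional `worksim_rng` source (scripted scenarios); `NULL`
#'   draws from the global RNG, so call `set.seed()` beforehand for
#'   reproducible runs.
#' @param attr_seed optional integer: when set, entrant attributes come from
#'   a counter-based substream keyed on this seed and the spawning time-step,
#'   so experimental conditions sharing `attr_seed` (and an arrival schedule)
#'   see identical entrant populations (variance reduction for condition
#'   contrasts).
#' @param trace logical: record every stage transition (t, worker id, from,
#'   to, tag) for trace-level inspection via [event_log()].
#' @param check_invariants logical: verify worker conservation, stage
#'   uniqueness, treatment occupancy and exact ledger conservation at the end
#'   of every step, aborting with a diagnostic on breach.
#' @return An environment of class `worksim_state` with `t = 0` and no
#'   workers.
#' @seealso [advance()], [run_simulation()]
#' @export
new_system_state <- function(levers = default_levers(), rng = NULL,
                             attr_seed = NULL, trace = FALSE,
                             check_invariants = FALSE) {
  s <- new.env(parent = emptyenv())
  s$levers_snapshot <- levers
  s$t <- 0L
  s$n <- 0L
  s$cap <- 4096L
  s$pop <- empty_population(s$cap)
  s$ev <- data.table::data.table(id = integer(1024L), t = integer(1024L),
                                 code = integer(1024L))
  s$ev_n <- 0L
  s$live_ids <- integer(0)
  s$queue <- integer(0); s$qhead <- 0L
  s$current_arrival_rate <- as.integer(levers$arrival_rate)
  s$spawned_total <- 0L; s$exited_total <- 0L
  s$n_full_rtw <- 0L; s$n_partial_rtw <- 0L; s$n_failed_rtw <- 0L
  s$n_disputes <- 0L; s$n_terminated <- 0L
  # exit accumulators for O(live) snapshots
  s$sum_dur <- 0; s$n_dur <- 0L; s$sum_dur_term <- 0; s$n_dur_term <- 0L
  s$ex_trust_acc_sum <- 0; s$ex_trust_acc_n <- 0L
  s$ex_trust_rej_sum <- 0; s$ex_trust_rej_n <- 0L
  # system ledgers, integer cents
  s$sys_medical <- 0; s$sys_treatment <- 0; s$sys_wage <- 0
  s$sys_occ_rehab <- 0; s$sys_advertising <- 0
  s$rng <- rng
  s$attr_seed <- attr_seed
  s$trace <- isTRUE(trace)
  s$trace_log <- list()
  s$check <- isTRUE(check_invariants)
  class(s) <- "worksim_state"
  s
}

#' @export
print.worksim_state <- function(x, ...) {
  cat(sprintf(
    "<worksim state: t = %d, %d live / %d spawned, queue %d, total cost $%.2f>\n",
    x$t, length(x$live_ids), x$spawned_total,
    length(x$queue) - x$qhead, total_cost_cents(x) / 100))
  invisible(x)
}

total_cost_cents <- function(s) {
  s$sys_medical + s$sys_treatment + s$sys_wage + s$sys_occ_rehab +
    s$sys_advertising
}

grow_state <- function(s, need) {
  while (s$cap < need) {
    s$pop <- data.table::rbindlist(list(s$pop, empty_population(s$cap)))
    s$cap <- s$cap * 2L
  }
  invisible(s)
}

record_trace <- function(s, ids, from, to, tag) {
  if (!s$trace || !length(ids)) return(invisible(NULL))
  s$trace_log[[length(s$trace_log) + 1L]] <-
    data.frame(t = s$t, worker_id = ids, from_stage = from, to_stage = to,
               event_tag = tag, stringsAsFactors = FALSE)
  invisible(NULL)
}

#' Retrieve the recorded event log of a traced run
#'
#' @param state a `worksim_state` created with `trace = TRUE`.
#' @return A data.frame with columns `t`, `worker_id`, `from_stage`,
#'   `to_stage`, `event_tag`, one row per stage transition in order.
#' @export
event_log <- function(state) {
  if (!length(state$trace_log)) {
    return(data.frame(t = integer(0), worker_id = integer(0),
                      from_stage = character(0), to_stage = character(0),
                      event_tag = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, state$trace_log)
  rownames(out) <- NULL
  out
}

# vectorized psychological event: update trust/satisfaction with clamping
# and (for discrete events) append to the population event memory
apply_event_vec <- function(s, ids, event, levers, log_memory = TRUE) {
  if (!length(ids)) return(invisible(NULL))
  p <- s$pop
  d <- levers$psych_deltas[[event]]
  data.table::set(p, ids, "trust", clamp100(p$trust[ids] + d[["trust"]]))
  data.table::set(p, ids, "satisfaction",
                  clamp100(p$satisfaction[ids] + d[["satisfaction"]]))
  if (log_memory) {
    need <- s$ev_n + length(ids)
    while (nrow(s$ev) < need) {
      s$ev <- data.table::rbindlist(
        list(s$ev, data.table::data.table(id = integer(nrow(s$ev)),
                                          t = integer(nrow(s$ev)),
                                          code = integer(nrow(s$ev)))))
    }
    idx <- (s$ev_n + 1L):need
    data.table::set(s$ev, idx, "id", as.integer(ids))
    data.table::set(s$ev, idx, "t", s$t)
    data.table::set(s$ev, idx, "code", match(event, PSYCH_EVENTS))
    s$ev_n <- need
  }
  invisible(NULL)
}

#' A worker's bounded event memory
#'
#' Returns the discrete events recorded against one worker during an engine
#' run, as (time-step, event) pairs, capped at the configured memory span:
#' events beyond the most recent `memory_span` entries are forgotten.
#'
#' @param state a `worksim_state`.
#' @param id worker id.
#' @param span memory capacity (defaults to the run's `memory_span` lever).
#' @return A data.frame with columns `t` and `event`, oldest first.
#' @export
worker_memory <- function(state, id,
                          span = state$levers_snapshot$memory_span) {
  s <- state
  idx <- which(s$ev$id[seq_len(s$ev_n)] == id)
  if (length(idx) > span) {
    idx <- idx[seq.int(length(idx) - span + 1L, length(idx))]
  }
  data.frame(t = s$ev$t[idx], event = PSYCH_EVENTS[s$ev$code[idx]],
             stringsAsFactors = FALSE)
}

enqueue_lodgement <- function(s, ids) {
  if (!length(ids)) return(invisible(NULL))
  data.table::set(s$pop, ids, "stage", ST_LODGEMENT)
  data.table::set(s$pop, ids, "queue_enter", s$t)
  s$queue <- c(s$queue, ids)
  invisible(NULL)
}

queue_length <- function(s) length(s$queue) - s$qhead

# Pop up to k claims, FIFO, restricted to claims lodged before the current
# step: a claim always waits in lodgement for at least one step ("held there
# for the duration it took their claim to be assessed"). queue_enter values
# are non-decreasing along the queue, so the eligible claims are a prefix.
pop_lodgement <- function(s, k) {
  k <- min(k, queue_length(s))
  if (k <= 0) return(integer(0))
  cand <- s$queue[(s$qhead + 1L):(s$qhead + k)]
  k <- sum(s$pop$queue_enter[cand] < s$t)
  if (k <= 0) return(integer(0))
  ids <- cand[seq_len(k)]
  s$qhead <- s$qhead + k
  if (s$qhead > 8192L) {
    s$queue <- s$queue[-seq_len(s$qhead)]
    s$qhead <- 0L
  }
  ids
}

mark_exit <- function(s, ids, reason) {
  if (!length(ids)) return(invisible(NULL))
  p <- s$pop
  data.table::set(p, ids, "stage", ST_EXITED)
  data.table::set(p, ids, "exit_reason", reason)
  s$exited_total <- s$exited_total + length(ids)
  acc <- p$accepted[ids]
  t_acc <- ids[acc == ACC_ACCEPTED]
  t_rej <- ids[acc == ACC_REJECTED]
  s$ex_trust_acc_sum <- s$ex_trust_acc_sum + sum(p$trust[t_acc])
  s$ex_trust_acc_n <- s$ex_trust_acc_n + length(t_acc)
  s$ex_trust_rej_sum <- s$ex_trust_rej_sum + sum(p$trust[t_rej])
  s$ex_trust_rej_n <- s$ex_trust_rej_n + length(t_rej)
  with_claim <- ids[!is.na(p$claim_start[ids])]
  if (length(with_claim)) {
    dur <- s$t - p$claim_start[with_claim]
    data.table::set(p, with_claim, "claim_dur", as.numeric(dur))
    s$sum_dur <- s$sum_dur + sum(dur)
    s$n_dur <- s$n_dur + length(dur)
    if (reason == EXIT_TERMINATED) {
      s$sum_dur_term <- s$sum_dur_term + sum(dur)
      s$n_dur_term <- s$n_dur_term + length(dur)
    }
  }
  invisible(NULL)
}

#' Inject a pre-built worker into the system
#'
#' Place a single worker (see [make_worker()]) into the population at its
#' current stage. Used by scenario scripts to start a trajectory from a known
#' attribute vector rather than a sampled one.
#'
#' @param state a `worksim_state`.
#' @param worker an `injured_worker`.
#' @return The worker's id in the population, invisibly.
#' @export
inject_worker <- function(state, worker) {
  s <- state
  grow_state(s, s$n + 1L)
  i <- s$n + 1L
  s$n <- i
  s$spawned_total <- s$spawned_total + 1L
  p <- s$pop
  data.table::set(p, i, "injury", match(worker$injury_type, INJURY_TYPES))
  data.table::set(p, i, "health", worker$health)
  data.table::set(p, i, "trust", worker$trust)
  data.table::set(p, i, "satisfaction", worker$satisfaction)
  data.table::set(p, i, "fight", worker$fight_appetite)
  data.table::set(p, i, "resp", worker$responsiveness)
  data.table::set(p, i, "salary", worker$salary)
  data.table::set(p, i, "expect", worker$expectation_wait)
  data.table::set(p, i, "accepted", ACC_PENDING)
  st <- match(worker$stage, STAGE_NAMES)
  if (is.na(st)) st <- ST_GP
  data.table::set(p, i, "stage", st)
  if (st == ST_LODGEMENT) {
    data.table::set(p, i, "queue_enter", s$t)
    s$queue <- c(s$queue, i)
  }
  s$live_ids <- c(s$live_ids, i)
  record_trace(s, i, "general_population", STAGE_NAMES[st], "injected")
  invisible(i)
}

spawn_cohort_internal <- function(s, levers, n_new) {
  n_new <- as.integer(n_new)
  if (n_new <= 0L) return(integer(0))
  grow_state(s, s$n + n_new)
  if (!is.null(s$attr_seed) && (is.null(s$rng) || !s$rng$scripted)) {
    u <- worker_attr_unifs(s$attr_seed, s$t, n_new)
  } else {
    u <- matrix(rng_unif(s$rng, n_new * N_ATTR_DRAWS), nrow = n_new,
                byrow = TRUE)
  }
  a <- worker_attrs_from_unifs(u, levers)
  ids <- s$n + seq_len(n_new)
  s$n <- s$n + n_new
  s$spawned_total <- s$spawned_total + n_new
  p <- s$pop
  data.table::set(p, ids, "injury", match(a$injury_type, INJURY_TYPES))
  data.table::set(p, ids, "health", a$health)
  data.table::set(p, ids, "trust", a$trust)
  data.table::set(p, ids, "satisfaction", a$satisfaction)
  data.table::set(p, ids, "fight", a$fight_appetite)
  data.table::set(p, ids, "resp", a$responsiveness)
  data.table::set(p, ids, "salary", a$salary)
  data.table::set(p, ids, "expect", a$expectation_wait)
  data.table::set(p, ids, "stage",
                  ifelse(a$start_stage == "gp", ST_GP, ST_ED))
  data.table::set(p, ids, "accepted", ACC_PENDING)
  s$live_ids <- c(s$live_ids, ids)
  record_trace(s, ids, "general_population", STAGE_NAMES[p$stage[ids]],
               "injured")
  ids
}

#' Advance the system by one time-step
#'
#' Executes the fixed phase order (spawning, triage assessments, workplace
#' re-checks, capacity-bounded claim adjudication, dispute resolutions,
#' treatment with denial and cost accrual, return-to-work attempts, benefit
#' termination, wage accrual, psychology updates) and increments the clock.
#'
#' @param state a `worksim_state`, modified in place.
#' @param levers a `worksim_levers` list.
#' @return The state, invisibly.
#' @export
advance <- function(state, levers = state$levers_snapshot) {
  s <- state
  s$t <- s$t + 1L
  t <- s$t
  rng <- s$rng
  set_ <- data.table::set

  ## phase 1: spawn ---------------------------------------------------------
  if (isTRUE(levers$arrival_variation_enabled) && t %% 50L == 0L) {
    u <- rng_unif(rng, 1L)
    s$current_arrival_rate <- max(0L, s$current_arrival_rate +
                                    if (u < 0.5) -1L else 1L)
  }
  n_new <- s$current_arrival_rate
  if (levers$mass_incident_step > 0 && t == levers$mass_incident_step) {
    n_new <- n_new + levers$mass_incident_size
  }
  spawn_cohort_internal(s, levers, n_new)

  p <- s$pop
  live <- s$live_ids
  stg <- p$stage[live]

  ## phase 2: GP / ED assessments ------------------------------------------
  gp <- live[stg == ST_GP]
  if (length(gp)) {
    u_correct <- rng_unif(rng, length(gp))
    u_cost <- rng_unif(rng, length(gp))
    set_(p, gp, "led_gp", p$led_gp[gp] +
           round(q_cost(u_cost, levers$gp_cost_mean, levers$gp_cost_sd),
                 2) * 100)
    to_lodge <- gp_referral(p$health[gp], levers, u = u_correct) ==
      "to_lodgement"
    record_trace(s, gp[to_lodge], "gp", "claim_lodgement", "gp_referral")
    record_trace(s, gp[!to_lodge], "gp", "workplace_check", "gp_referral")
    enqueue_lodgement(s, gp[to_lodge])
    set_(p, gp[!to_lodge], "stage", ST_WORKPLACE)
  }
  ed <- live[stg == ST_ED]
  if (length(ed)) {
    set_(p, ed, "led_ed", p$led_ed[ed] + levers$ed_cost * 100)
    to_lodge <- ed_referral(p$health[ed], levers) == "to_lodgement"
    record_trace(s, ed[to_lodge], "emergency", "claim_lodgement",
                 "ed_referral")
    record_trace(s, ed[!to_lodge], "emergency", "workplace_check",
                 "ed_referral")
    enqueue_lodgement(s, ed[to_lodge])
    set_(p, ed[!to_lodge], "stage", ST_WORKPLACE)
  }

  ## phase 3: workplace re-checks ------------------------------------------
  wp <- live[p$stage[live] == ST_WORKPLACE]
  if (length(wp)) {
    u_drift <- rng_unif(rng, length(wp))
    set_(p, wp, "health", clamp100(
      p$health[wp] + pmax(0, stats::qnorm(u_drift,
                                          levers$waitlist_drift_mean,
                                          levers$waitlist_drift_sd))))
    back <- p$health[wp] <= levers$claim_threshold
    back_ids <- wp[back]
    out_ids <- wp[!back]
    apply_event_vec(s, back_ids, "sent_back_from_workplace", levers)
    record_trace(s, back_ids, "workplace_check", "claim_lodgement",
                 "sent_back")
    enqueue_lodgement(s, back_ids)
    record_trace(s, out_ids, "workplace_check", "exited", "recovered")
    mark_exit(s, out_ids, EXIT_RECOVERED_NO_CLAIM)
  }

  ## phase 4: claim adjudication -------------------------------------------
  cap_mult <- 1
  if (isTRUE(levers$capacity_variation_enabled)) {
    cap_mult <- if (rng_unif(rng, 1L) < 0.9) 1 else 0.5
  }
  k <- floor(levers$claims_processing_capacity * cap_mult)
  adj <- pop_lodgement(s, k)
  if (length(adj)) {
    u_acc <- rng_unif(rng, length(adj))
    acc <- adjudicate_claims(INJURY_TYPES[p$injury[adj]], levers, u = u_acc)
    acc_ids <- adj[acc]
    den_ids <- adj[!acc]
    if (length(acc_ids)) {
      set_(p, acc_ids, "accepted", ACC_ACCEPTED)
      first <- acc_ids[is.na(p$claim_start[acc_ids])]
      set_(p, first, "claim_start", t)
      xfer <- acc_ids[!p$transferred[acc_ids]]
      if (length(xfer)) {
        s$sys_medical <- s$sys_medical + sum(p$led_gp[xfer] + p$led_ed[xfer])
        set_(p, xfer, "transferred", TRUE)
      }
      set_(p, acc_ids, "stage", ST_ACCEPTED)
      record_trace(s, acc_ids, "claim_lodgement", "claim_accepted_waiting",
                   "claim_accepted")
    }
    if (length(den_ids)) {
      set_(p, den_ids, "accepted", ACC_REJECTED)
      apply_event_vec(s, den_ids, "claim_denied", levers)
      pr <- dispute_probability(p$fight[den_ids], p$trust[den_ids], levers)
      u_d <- rng_unif(rng, length(den_ids))
      disp <- u_d < pr & p$dispute_count[den_ids] < levers$dispute_max_repeats
      d_ids <- den_ids[disp]
      g_ids <- den_ids[!disp]
      if (length(d_ids)) {
        set_(p, d_ids, "stage", ST_DISPUTE)
        set_(p, d_ids, "dispute_kind", DK_CLAIM)
        set_(p, d_ids, "dispute_enter", t)
        set_(p, d_ids, "dispute_count", p$dispute_count[d_ids] + 1L)
        s$n_disputes <- s$n_disputes + length(d_ids)
        record_trace(s, d_ids, "claim_lodgement", "dispute", "claim_denied")
      }
      record_trace(s, g_ids, "claim_lodgement", "exited", "claim_denied")
      mark_exit(s, g_ids, EXIT_DENIED_GAVE_UP)
    }
  }

  ## phase 5: dispute resolutions ------------------------------------------
  live <- s$live_ids
  dis <- live[p$stage[live] == ST_DISPUTE &
                t - p$dispute_enter[live] >= levers$dispute_duration]
  if (length(dis)) {
    u_res <- rng_unif(rng, length(dis))
    won <- resolve_disputes(length(dis), levers, u = u_res)
    kind <- p$dispute_kind[dis]
    # claim disputes: won -> back of the lodgement queue to try again
    cw <- dis[won & kind == DK_CLAIM]
    if (length(cw)) {
      apply_event_vec(s, cw, "dispute_won", levers)
      set_(p, cw, "accepted", ACC_PENDING)
      set_(p, cw, "dispute_kind", DK_NONE)
      record_trace(s, cw, "dispute", "claim_lodgement", "dispute_won")
      enqueue_lodgement(s, cw)
    }
    cl <- dis[!won & kind == DK_CLAIM]
    if (length(cl)) {
      apply_event_vec(s, cl, "dispute_lost", levers)
      set_(p, cl, "dispute_kind", DK_NONE)
      record_trace(s, cl, "dispute", "exited", "dispute_lost")
      mark_exit(s, cl, EXIT_DISPUTE_LOST)
    }
    # treatment disputes: won -> straight back toward treatment; lost ->
    # re-entry through the claim-acceptance pathway with a further psych hit
    tw <- dis[won & kind == DK_TREATMENT]
    if (length(tw)) {
      apply_event_vec(s, tw, "dispute_won", levers)
      set_(p, tw, "dispute_kind", DK_NONE)
      set_(p, tw, "stage", ST_ACCEPTED)
      record_trace(s, tw, "dispute", "claim_accepted_waiting", "dispute_won")
    }
    tl <- dis[!won & kind == DK_TREATMENT]
    if (length(tl)) {
      apply_event_vec(s, tl, "dispute_lost", levers)
      set_(p, tl, "dispute_kind", DK_NONE)
      set_(p, tl, "stage", ST_ACCEPTED)
      record_trace(s, tl, "dispute", "claim_accepted_waiting",
                   "dispute_lost")
    }
  }

  ## phase 6: treatment -----------------------------------------------------
  live <- s$live_ids
  treat_cap <- floor(levers$treatment_capacity * cap_mult)
  in_treat <- live[p$stage[live] == ST_TREATMENT]
  if (length(in_treat) > treat_cap) {
    # capacity shock: latest-admitted workers wait in the accepted area
    excess <- in_treat[order(p$claim_start[in_treat],
                             decreasing = TRUE)][seq_len(length(in_treat) -
                                                           treat_cap)]
    set_(p, excess, "stage", ST_ACCEPTED)
    record_trace(s, excess, "treatment", "claim_accepted_waiting",
                 "capacity_shock")
    in_treat <- in_treat[!in_treat %in% excess]
  }
  free <- treat_cap - length(in_treat)
  if (free > 0) {
    waiting <- live[p$stage[live] == ST_ACCEPTED]
    if (length(waiting)) {
      waiting <- waiting[order(p$claim_start[waiting], waiting)]
      admit <- waiting[seq_len(min(free, length(waiting)))]
      set_(p, admit, "stage", ST_TREATMENT)
      record_trace(s, admit, "claim_accepted_waiting", "treatment",
                   "admitted")
      in_treat <- c(in_treat, admit)
    }
  }
  if (length(in_treat)) {
    nt <- length(in_treat)
    u_deny <- rng_unif(rng, nt)
    u_eps <- rng_unif(rng, nt)
    denied <- u_deny < levers$treatment_denial_rate
    eps <- q_noise(u_eps, levers$treatment_noise)
    idx_ok <- in_treat[!denied]
    idx_no <- in_treat[denied]
    if (length(idx_ok)) {
      set_(p, idx_ok, "health",
           treat_step(p$health[idx_ok], p$resp[idx_ok], levers,
                      eps = eps[!denied]))
      u_cost <- rng_unif(rng, length(idx_ok))
      cost_c <- sample_treatment_cost(length(idx_ok), levers,
                                      u = u_cost) * 100
      set_(p, idx_ok, "led_treat", p$led_treat[idx_ok] + cost_c)
      s$sys_treatment <- s$sys_treatment + sum(cost_c)
    }
    if (length(idx_no)) {
      # denied: no systematic improvement, random change only, no cost
      set_(p, idx_no, "health", clamp100(p$health[idx_no] + eps[denied]))
      apply_event_vec(s, idx_no, "treatment_denied", levers)
      pr <- dispute_probability(p$fight[idx_no], p$trust[idx_no], levers)
      u_d <- rng_unif(rng, length(idx_no))
      disp <- u_d < pr & p$dispute_count[idx_no] < levers$dispute_max_repeats
      d_ids <- idx_no[disp]
      if (length(d_ids)) {
        set_(p, d_ids, "stage", ST_DISPUTE)
        set_(p, d_ids, "dispute_kind", DK_TREATMENT)
        set_(p, d_ids, "dispute_enter", t)
        set_(p, d_ids, "dispute_count", p$dispute_count[d_ids] + 1L)
        s$n_disputes <- s$n_disputes + length(d_ids)
        record_trace(s, d_ids, "treatment", "dispute", "treatment_denied")
      }
    }
  }

  ## phase 7: return to work -----------------------------------------------
  live <- s$live_ids
  # (i) partial returners at work: health drifts up at the waitlist rate;
  #     conversion to full RTW at the claim threshold
  pool <- live[p$stage[live] == ST_RTW_POOL]
  if (length(pool)) {
    u_drift <- rng_unif(rng, length(pool))
    set_(p, pool, "health", clamp100(
      p$health[pool] + pmax(0, stats::qnorm(u_drift,
                                            levers$waitlist_drift_mean,
                                            levers$waitlist_drift_sd))))
    done <- pool[p$health[pool] >= levers$claim_threshold]
    if (length(done)) {
      s$n_full_rtw <- s$n_full_rtw + length(done)
      record_trace(s, done, "rtw_pool", "exited", "full_rtw")
      mark_exit(s, done, EXIT_FULL_RTW)
    }
  }
  # (ii) full RTW from treatment
  tr <- live[p$stage[live] == ST_TREATMENT]
  gate <- rtw_gate(p$health[tr], levers)
  full <- tr[gate == "to_rtw_pool"]
  if (length(full)) {
    s$n_full_rtw <- s$n_full_rtw + length(full)
    record_trace(s, full, "treatment", "rtw_pool", "full_rtw")
    record_trace(s, full, "rtw_pool", "exited", "rtw_exit")
    mark_exit(s, full, EXIT_FULL_RTW)
  }
  # (iii) employer attempts under the encourage policy
  att <- tr[gate == "to_employer_attempt"]
  if (length(att)) {
    u_ready <- rng_unif(rng, length(att))
    readiness <- readiness_with_advertising(
      u_ready * levers$employer_readiness_max, levers)
    shortfall <- levers$claim_threshold - p$health[att]
    ok <- readiness >= shortfall
    occ_left <- if (isTRUE(levers$occ_rehab_enabled))
      levers$occ_rehab_capacity else 0
    need_occ <- which(!ok)
    occ_take <- need_occ[seq_len(min(length(need_occ), occ_left))]
    partial <- att[ok]
    occ_ids <- att[occ_take]
    failed <- att[!ok]
    failed <- failed[!failed %in% occ_ids]
    if (length(occ_ids)) {
      s$sys_occ_rehab <- s$sys_occ_rehab + length(occ_ids) *
        levers$occ_rehab_cost * 100
    }
    go <- c(partial, occ_ids)
    if (length(go)) {
      set_(p, go, "stage", ST_RTW_POOL)
      s$n_partial_rtw <- s$n_partial_rtw + length(go)
      record_trace(s, partial, "treatment", "rtw_pool", "partial_rtw")
      record_trace(s, occ_ids, "treatment", "rtw_pool",
                   "partial_rtw_occ_rehab")
    }
    if (length(failed)) {
      set_(p, failed, "failed_rtw", p$failed_rtw[failed] + 1L)
      s$n_failed_rtw <- s$n_failed_rtw + length(failed)
      record_trace(s, failed, "treatment", "treatment", "failed_rtw")
    }
  }

  ## phase 8: termination checks -------------------------------------------
  live <- s$live_ids
  act <- live[p$accepted[live] == ACC_ACCEPTED & p$stage[live] != ST_EXITED]
  term <- act[check_termination(p$claim_start[act], t, levers)]
  if (length(term)) {
    s$n_terminated <- s$n_terminated + length(term)
    record_trace(s, term, STAGE_NAMES[p$stage[term]], "exited", "terminated")
    mark_exit(s, term, EXIT_TERMINATED)
  }

  ## phase 9: wage accrual for accepted claims off full work ----------------
  live <- s$live_ids
  stg <- p$stage[live]
  on_benefit <- live[p$accepted[live] == ACC_ACCEPTED & stg != ST_EXITED]
  if (length(on_benefit)) {
    fitness <- numeric(length(on_benefit))
    at_work <- p$stage[on_benefit] == ST_RTW_POOL
    fitness[at_work] <- pmin(1, p$health[on_benefit][at_work] / 100)
    wage_c <- accrue_wage_cost(p$salary[on_benefit], levers, fitness) * 100
    set_(p, on_benefit, "led_wage", p$led_wage[on_benefit] + wage_c)
    s$sys_wage <- s$sys_wage + sum(wage_c)
  }
  if (levers$advertising_spend > 0) {
    s$sys_advertising <- s$sys_advertising + levers$advertising_spend * 100
  }

  ## phase 10: psychology updates ------------------------------------------
  live <- s$live_ids
  in_disp <- live[p$stage[live] == ST_DISPUTE]
  apply_event_vec(s, in_disp, "in_dispute_step", levers, log_memory = FALSE)
  queued <- live[p$stage[live] == ST_LODGEMENT &
                   (t - p$queue_enter[live]) > p$expect[live]]
  apply_event_vec(s, queued, "wait_exceeded_expectation", levers,
                  log_memory = FALSE)
  if (isTRUE(levers$mistrust_contagion_enabled)) {
    for (st_code in c(ST_LODGEMENT, ST_DISPUTE)) {
      grp <- live[p$stage[live] == st_code]
      if (length(grp) >= 2) {
        u_sel <- rng_unif(rng, length(grp))
        u_peer <- rng_unif(rng, length(grp))
        sel <- u_sel < levers$mistrust_contagion_prob
        if (any(sel)) {
          peers <- grp[pmin(length(grp),
                            1L + floor(u_peer[sel] * length(grp)))]
          data.table::set(p, grp[sel], "trust",
                          pmin(p$trust[grp[sel]], p$trust[peers]))
        }
      }
    }
  }

  ## retire exited workers from the live index ------------------------------
  s$live_ids <- s$live_ids[p$stage[s$live_ids] != ST_EXITED]

  if (s$check) check_state_invariants(s, levers, treat_cap)
  invisible(s)
}

check_state_invariants <- function(s, levers, treat_cap) {
  p <- s$pop
  live <- s$live_ids
  if (length(live) + s$exited_total != s$spawned_total) {
    stop("worker conservation breached at t = ", s$t, ": ", length(live),
         " live + ", s$exited_total, " exited != ", s$spawned_total,
         " spawned", call. = FALSE)
  }
  if (anyDuplicated(live)) {
    stop("worker appears twice in the live index at t = ", s$t,
         call. = FALSE)
  }
  if (any(p$stage[live] == ST_EXITED)) {
    stop("exited worker still live at t = ", s$t, call. = FALSE)
  }
  occ <- sum(p$stage[live] == ST_TREATMENT)
  if (occ > treat_cap) {
    stop("treatment occupancy ", occ, " exceeds capacity ", treat_cap,
         " at t = ", s$t, call. = FALSE)
  }
  idx <- seq_len(s$n)
  if (s$sys_treatment != sum(p$led_treat[idx])) {
    stop("treatment ledger conservation breached at t = ", s$t,
         call. = FALSE)
  }
  if (s$sys_wage != sum(p$led_wage[idx])) {
    stop("wage ledger conservation breached at t = ", s$t, call. = FALSE)
  }
  xfer <- idx[p$transferred[idx]]
  if (s$sys_medical != sum(p$led_gp[xfer] + p$led_ed[xfer])) {
    stop("medical ledger conservation breached at t = ", s$t, call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a complete simulation
#'
#' Creates an empty system, advances it `n_steps` times and collects the
#' per-step monitors.
#'
#' @param levers a `worksim_levers` list.
#' @param n_steps number of time-steps (default 2000).
#' @param seed integer seed for the run's random stream; `NULL` leaves the
#'   global RNG untouched.
#' @param attr_seed,trace,check_invariants passed to [new_system_state()].
#' @param snapshot_every record a monitor row every this many steps (the
#'   final step is always recorded; cumulative monitors are exact regardless
#'   of thinning). Default 1 = full per-step series.
#' @return A list of class `worksim_run`: `series` (data.frame of
#'   [snapshot()] rows, one per step), `final` (the last row), `levers`,
#'   `seed`, and `state` (the end-of-run `worksim_state`).
#' @examples
#' run <- run_simulation(default_levers(), n_steps = 50, seed = 1)
#' run$final$n_in_system
#' @export
run_simulation <- function(levers = default_levers(), n_steps = 2000,
                           seed = NULL, attr_seed = NULL, trace = FALSE,
                           check_invariants = FALSE, snapshot_every = 1L) {
  viol <- validate_levers(levers)
  if (length(viol)) {
    stop("invalid levers:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  state <- new_system_state(levers, attr_seed = attr_seed, trace = trace,
                            check_invariants = check_invariants)
  keep <- unique(c(seq.int(snapshot_every, n_steps, by = snapshot_every),
                   n_steps))
  series <- matrix(NA_real_, nrow = length(keep),
                   ncol = length(METRIC_COLS),
                   dimnames = list(NULL, METRIC_COLS))
  k <- 0L
  for (i in seq_len(n_steps)) {
    advance(state, levers)
    if (i == keep[k + 1L]) {
      k <- k + 1L
      series[k, ] <- snapshot_row(state)
    }
  }
  series <- as.data.frame(series)
  out <- list(series = series, final = series[nrow(series), , drop = FALSE],
              levers = levers, seed = seed, state = state)
  class(out) <- "worksim_run"
  out
}

#' @export
print.worksim_run <- function(x, ...) {
  f <- x$final
  cat(sprintf("<worksim run: %d steps, seed %s>\n", nrow(x$series),
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  final: %d in system; mean health %.1f, trust %.1f, satisfaction %.1f\n",
              f$n_in_system, f$mean_health, f$mean_trust,
              f$mean_satisfaction))
  cat(sprintf("  RTW full/partial/failed: %d/%d/%d; disputes %d; terminated %d\n",
              f$n_full_rtw, f$n_partial_rtw, f$n_failed_rtw, f$n_disputes,
              f$n_terminated))
  cat(sprintf("  cum cost $%.2f (treatment %.2f, wage %.2f, medical %.2f, occ rehab %.2f)\n",
              f$cum_total_cost, f$cum_treatment_cost, f$cum_wage_cost,
              f$cum_medical_cost, f$cum_occ_rehab_cost))
  cat(sprintf("  mean claim duration at exit: %.1f steps\n",
              f$mean_claim_duration_at_exit))
  invisible(x)
}
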