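# Worker psychology: trust/satisfaction dynamics and the dispute decision.

clamp100 <- function(x) pmin(100, pmax(0, x))

#' Probability that a worker disputes an unfavourable decision
#'
#' The dispute likelihood rises with appetite for fighting decisions and
#' falls with trust in the system:
#' `p = (fight/100)^a * (1 - trust/100)^b`, with exponents `a`, `b`
#' defaulting to 1 — the minimal functional form with both monotonicities.
#' A fully trusting worker never disputes; a zero-trust worker with maximal
#' fight always does.
#'
#' @param fight_appetite,trust points on `[0, 100]` scales (vectorized).
#' @param levers optional `worksim_levers` list supplying the exponents
#'   `dispute_fight_exp` and `dispute_trust_exp`.
#' @return Probability vector in `[0, 1]`.
#' @examples
#' dispute_probability(50, 50)   # 0.25
#' @export
dispute_probability <- function(fight_appetite, trust, levers = NULL) {
  a <- if (is.null(levers)) 1 else levers$dispute_fight_exp
  b <- if (is.null(levers)) 1 else levers$dispute_trust_exp
  (fight_appetite / 100)^a * (1 - trust / 100)^b
}

PSYCH_EVENTS <- c("claim_denied", "treatment_denied",
                  "sent_back_from_workplace", "wait_exceeded_expectation",
                  "in_dispute_step", "dispute_lost", "dispute_won")

#' Apply a psychological event to a worker
#'
#' Updates trust and satisfaction by the event's configured deltas, clamping
#' both to `[0, 100]`, and appends the event to the worker's bounded memory
#' (evicting the oldest entry beyond `memory_span`).
#'
#' @param worker an `injured_worker` (see [make_worker()]).
#' @param event one of `r paste0('\x60', PSYCH_EVENTS, '\x60', collapse = ", ")`.
#' @param t current time-step, recorded in memory.
#' @param deltas delta table (named list of `c(trust=, satisfaction=)`);
#'   defaults to [default_psych_deltas()].
#' @return The updated worker.
#' @examples
#' w <- make_worker(trust = 3)
#' apply_psych_event(w, "claim_denied", t = 1)$trust   # clamped at 0
#' @export
apply_psych_event <- function(worker, event, t,
                              deltas = default_psych_deltas()) {
  if (!event %in% names(deltas)) stop("unknown psych event: ", event,
                                      call. = FALSE)
  d <- deltas[[event]]
  worker$trust <- clamp100(worker$trust + d[["trust"]])
  worker$satisfaction <- clamp100(worker$satisfaction + d[["satisfaction"]])
  worker$memory <- rbind(worker$memory,
                         data.frame(t = as.integer(t), event = event,
                                    stringsAsFactors = FALSE))
  if (nrow(worker$memory) > worker$memory_span) {
    keep <- seq.int(nrow(worker$memory) - worker$memory_span + 1L,
                    nrow(worker$memory))
    worker$memory <- worker$memory[keep, , drop = FALSE]
    rownames(worker$memory) <- NULL
  }
  worker
}
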