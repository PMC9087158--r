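# Deterministic micro-scenarios.
#
# A scenario script fixes a worker's entry attributes, the lever settings,
# and the exact sequence of uniform draws the engine will consume; the
# trajectory is then fully determined and its stage-transition trace can be
# compared against a hand-derived expectation. The scripted draws feed the
# same rng_unif() gate the production engine uses, so the code path under
# test is the production code path.

#' Load a scenario script
#'
#' @param path YAML file with keys `worker` (field overrides for
#'   [make_worker()]), `levers` (lever overrides), `n_steps`, `draws`
#'   (ordered uniforms consumed by the engine) and `expected_transitions`
#'   (list of `from`/`to`/`tag` records).
#' @return A list of class `worksim_scenario`.
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(!is.null(raw$n_steps), !is.null(raw$draws))
  sc <- list(worker = if (is.null(raw$worker)) list() else raw$worker,
             levers = if (is.null(raw$levers)) list() else raw$levers,
             n_steps = as.integer(raw$n_steps),
             draws = as.numeric(unlist(raw$draws)),
             expected = raw$expected_transitions)
  class(sc) <- "worksim_scenario"
  sc
}

#' Play a scenario script through the engine
#'
#' Builds a one-worker system with a scripted random source and advances it
#' for the scripted number of steps, recording every stage transition.
#'
#' @param scenario a `worksim_scenario` (see [load_scenario()]), or a path
#'   to a scenario YAML file.
#' @return A list: `trace` (the observed transition data.frame, as
#'   [event_log()]), `expected` (the script's expected transitions as a
#'   data.frame, or `NULL`), `state` (the final `worksim_state`).
#' @export
play_script <- function(scenario) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  levers <- do.call(default_levers, c(scenario$levers,
                                      list(arrival_rate = 0)))
  worker <- do.call(make_worker, scenario$worker)
  rng <- rng_source(scenario$draws)
  state <- new_system_state(levers, rng = rng, trace = TRUE,
                            check_invariants = TRUE)
  inject_worker(state, worker)
  for (i in seq_len(scenario$n_steps)) advance(state, levers)
  expected <- NULL
  if (!is.null(scenario$expected)) {
    expected <- do.call(rbind, lapply(scenario$expected, function(e) {
      data.frame(from_stage = e$from, to_stage = e$to,
                 event_tag = if (is.null(e$tag)) NA_character_ else e$tag,
                 stringsAsFactors = FALSE)
    }))
  }
  list(trace = event_log(state), expected = expected, state = state)
}
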