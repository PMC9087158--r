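# Factorial experiment runner.
#
# Conditions are lever settings crossed over a grid; replicates within a
# condition use distinct seeds, and the same replicate index uses the same
# seed in every condition (paired seeds). Entrant attribute streams are
# counter-based on the replicate seed, so every condition faces an identical
# entrant population — condition contrasts are then low-variance.

#' Define a factorial experiment
#'
#' @param factors named list: each element is a lever name mapped to a
#'   vector of levels; the design is the full cross of all levels.
#' @param n_reps replicates per condition (default 30).
#' @param n_steps simulation horizon per run (default 2000).
#' @param base_seed integer from which replicate seeds are derived
#'   deterministically.
#' @return A list of class `worksim_design` with a `conditions` data.frame
#'   (one row per condition, columns per factor, plus `condition` label).
#' @export
experiment_design <- function(factors, n_reps = 30, n_steps = 2000,
                              base_seed = 1) {
  stopifnot(length(factors) >= 1, n_reps >= 1, n_steps >= 1)
  conditions <- expand.grid(factors, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
  conditions$condition <- apply(conditions, 1, function(r) {
    paste(paste0(names(r), "=", r), collapse = ",")
  })
  d <- list(factors = factors, conditions = conditions,
            n_reps = as.integer(n_reps), n_steps = as.integer(n_steps),
            base_seed = as.integer(base_seed))
  class(d) <- "worksim_design"
  d
}

#' The default six-condition RTW policy matrix
#'
#' Crosses the return-to-work promotion policy (discourage, neutral,
#' encourage) with occupational rehabilitation support (off, on): six
#' conditions, compared on the eight outcome variables at the final step of
#' a 2000-step horizon.
#'
#' @inheritParams experiment_design
#' @return A `worksim_design`.
#' @examples
#' d <- default_matrix(n_reps = 2, n_steps = 100)
#' nrow(d$conditions)  # 6
#' @export
default_matrix <- function(n_reps = 30, n_steps = 2000, base_seed = 1) {
  experiment_design(
    factors = list(rtw_policy = c("discourage", "neutral", "encourage"),
                   occ_rehab_enabled = c(FALSE, TRUE)),
    n_reps = n_reps, n_steps = n_steps, base_seed = base_seed)
}

#' @export
print.worksim_design <- function(x, ...) {
  cat(sprintf("<worksim design: %d condition(s) x %d replicate(s), %d steps>\n",
              nrow(x$conditions), x$n_reps, x$n_steps))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

# replicate seeds, deterministic in base_seed, kept below 2^31
replicate_seed <- function(base_seed, rep) {
  (base_seed * 10007 + rep * 7919) %% 2147483647L
}

#' Run one experimental condition
#'
#' A single complete simulation under one lever setting, deterministic given
#' its seed.
#'
#' @param levers a `worksim_levers` list.
#' @param n_steps horizon.
#' @param seed run seed.
#' @param attr_seed optional entrant-stream seed for cross-condition pairing
#'   (defaults to `seed`).
#' @param snapshot_every monitor thinning (see [run_simulation()]).
#' @return A `worksim_run` (see [run_simulation()]).
#' @export
run_condition <- function(levers, n_steps, seed, attr_seed = seed,
                          snapshot_every = 1L) {
  run_simulation(levers, n_steps = n_steps, seed = seed,
                 attr_seed = attr_seed, snapshot_every = snapshot_every)
}

#' Run a full factorial experiment
#'
#' Runs every condition x replicate, collecting final-step outcomes into a
#' tidy table. A replicate that fails is recorded with its error message and
#' the remaining runs proceed.
#'
#' @param design a `worksim_design`.
#' @param base_levers lever settings shared by all conditions (factors
#'   override these per condition).
#' @param out optional CSV path for the per-replicate results.
#' @return A list of class `worksim_results`: `results` (one row per
#'   condition x replicate: factors, `rep`, `seed`, `error`, and the
#'   final-step outcomes) and `summary` (per-condition mean and standard
#'   error of each outcome).
#' @examples
#' d <- default_matrix(n_reps = 2, n_steps = 40)
#' r <- run_matrix(d)
#' @export
run_matrix <- function(design, base_levers = default_levers(), out = NULL) {
  conds <- design$conditions
  fnames <- names(design$factors)
  rows <- vector("list", nrow(conds) * design$n_reps)
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    lv <- base_levers
    for (f in fnames) lv[[f]] <- conds[[f]][ci]
    for (rep in seq_len(design$n_reps)) {
      k <- k + 1L
      seed <- replicate_seed(design$base_seed, rep)
      base <- conds[ci, , drop = FALSE]
      rownames(base) <- NULL
      base$rep <- rep
      base$seed <- seed
      res <- tryCatch({
        # the experiment consumes final-step outcomes; keep a coarse series
        run <- run_condition(lv, design$n_steps, seed,
                             snapshot_every = max(1L, design$n_steps %/% 8L))
        cbind(base, error = NA_character_, run$final, row.names = NULL)
      }, error = function(e) {
        fin <- as.data.frame(as.list(stats::setNames(
          rep(NA_real_, length(METRIC_COLS)), METRIC_COLS)))
        cbind(base, error = conditionMessage(e), fin, row.names = NULL)
      })
      rows[[k]] <- res
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- is.na(results$error)
  outs <- outcome_variables()
  agg <- lapply(split(results[ok, , drop = FALSE], results$condition[ok]),
                function(d) {
    means <- vapply(outs, function(v) mean(d[[v]]), numeric(1))
    ses <- vapply(outs, function(v) {
      stats::sd(d[[v]]) / sqrt(sum(!is.na(d[[v]])))
    }, numeric(1))
    cbind(d[1, c(fnames, "condition"), drop = FALSE],
          as.data.frame(as.list(c(stats::setNames(means, paste0("mean_", outs)),
                                  stats::setNames(ses, paste0("se_", outs))))),
          n_reps = nrow(d), row.names = NULL)
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  res <- list(results = results, summary = summary, design = design)
  class(res) <- "worksim_results"
  if (!is.null(out)) utils::write.csv(results, out, row.names = FALSE)
  res
}

#' @export
print.worksim_results <- function(x, ...) {
  cat(sprintf("<worksim experiment: %d run(s), %d condition(s)>\n",
              nrow(x$results), nrow(x$summary)))
  show <- c("condition", "mean_n_in_system",
            "mean_mean_claim_duration_at_exit", "mean_cum_total_cost")
  print(x$summary[, intersect(show, names(x$summary)), drop = FALSE],
        row.names = FALSE)
  invisible(x)
}
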