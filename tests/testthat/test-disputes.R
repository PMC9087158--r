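test_that("dispute probability is monotone in fight and trust with the stated boundaries", {
  expect_equal(dispute_probability(0, 100), 0)
  expect_equal(dispute_probability(100, 100), 0)   # full trust never disputes
  expect_equal(dispute_probability(100, 0), 1)
  expect_equal(dispute_probability(50, 50), 0.25)
  f <- seq(0, 100, by = 10)
  expect_true(all(diff(dispute_probability(f, 40)) > 0))
  tr <- seq(0, 90, by = 10)
  expect_true(all(diff(dispute_probability(60, tr)) < 0))
})

test_that("dispute resolution honours the configured success rate", {
  lv1 <- default_levers(dispute_success_rate = 1, dispute_duration = 1)
  r <- play_script(list(worker = list(health = 40, fight_appetite = 100,
                                      trust = 0, stage = "gp"),
                        levers = list(dispute_success_rate = 1,
                                      dispute_duration = 1),
                        n_steps = 3,
                        draws = c(0.05, 0.5, 0.95, 0.5, 0.999)))
  # forced success: back in the lodgement queue
  expect_true(any(r$trace$from_stage == "dispute" &
                    r$trace$to_stage == "claim_lodgement"))

  r0 <- play_script(list(worker = list(health = 40, fight_appetite = 100,
                                       trust = 0, stage = "gp"),
                         levers = list(dispute_success_rate = 0,
                                       dispute_duration = 1),
                         n_steps = 3,
                         draws = c(0.05, 0.5, 0.95, 0.5, 0.001)))
  expect_true(any(r0$trace$from_stage == "dispute" &
                    r0$trace$to_stage == "exited"))

  set.seed(14)
  won <- resolve_disputes(1e4, default_levers())
  expect_lt(abs(mean(won) - 0.5), 0.015)
})

test_that("psychological events shift trust/satisfaction with clamping and are remembered", {
  w <- make_worker(trust = 3)
  w <- apply_psych_event(w, "claim_denied", t = 1)
  expect_equal(w$trust, 0)            # clamped at the floor
  w2 <- make_worker(trust = 60)
  w2 <- apply_psych_event(w2, "claim_denied", t = 1)
  expect_lt(w2$trust, 60)
  w3 <- make_worker(trust = 60)
  w3 <- apply_psych_event(w3, "dispute_won", t = 1)
  expect_gte(w3$trust, 60)            # favourable events never reduce trust
  expect_equal(w3$memory$event, "dispute_won")
  expect_error(apply_psych_event(w3, "not_an_event", 1), "unknown")
})

test_that("worker memory is bounded by the memory span, evicting the oldest", {
  w <- make_worker(memory_span = 3)
  for (i in 1:5) w <- apply_psych_event(w, "claim_denied", t = i)
  expect_equal(nrow(w$memory), 3)
  expect_equal(w$memory$t, 3:5)
  # same semantics for engine-run memory
  r <- play_script(list(worker = list(health = 40, fight_appetite = 100,
                                      trust = 0, stage = "gp"),
                        levers = list(dispute_duration = 1,
                                      dispute_success_rate = 1),
                        n_steps = 3,
                        draws = c(0.05, 0.5, 0.95, 0.5, 0.5)))
  mem <- worker_memory(r$state, 1L)
  expect_true(all(mem$event %in% c("claim_denied", "dispute_won")))
  mem1 <- worker_memory(r$state, 1L, span = 1)
  expect_equal(nrow(mem1), 1)
})

test_that("populations exposed to more adverse events end with lower mean trust", {
  lv_low <- default_levers(treatment_denial_rate = 0)
  lv_high <- default_levers(treatment_denial_rate = 0.4)
  a <- run_simulation(lv_low, n_steps = 250, seed = 60, attr_seed = 60)
  b <- run_simulation(lv_high, n_steps = 250, seed = 60, attr_seed = 60)
  expect_gt(a$final$mean_trust, b$final$mean_trust)
})

test_that("raising the treatment denial rate raises disputes and lowers mean health", {
  # measured while claim cohorts are still recovering (a slowdown shifts
  # every cohort's health down at a fixed age; at stationarity the live
  # population's health distribution is insensitive to a uniform slowdown)
  lv_low <- default_levers(treatment_denial_rate = 0)
  lv_high <- default_levers(treatment_denial_rate = 0.5)
  a <- run_simulation(lv_low, n_steps = 100, seed = 61, attr_seed = 61)
  b <- run_simulation(lv_high, n_steps = 100, seed = 61, attr_seed = 61)
  expect_gt(b$final$n_disputes, a$final$n_disputes)
  expect_lt(b$final$mean_health, a$final$mean_health)
})

test_that("repeat disputes can be capped by configuration", {
  lv <- default_levers(dispute_max_repeats = 0)
  # with zero allowed disputes a denied claim always exits
  r <- play_script(list(worker = list(health = 40, fight_appetite = 100,
                                      trust = 0, stage = "gp"),
                        levers = list(dispute_max_repeats = 0),
                        n_steps = 2,
                        draws = c(0.05, 0.5, 0.95, 0.5)))
  expect_true(any(r$trace$from_stage == "claim_lodgement" &
                    r$trace$to_stage == "exited"))
})
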