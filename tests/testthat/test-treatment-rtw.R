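test_that("a treatment step closes 5% of the health gap, scaled by responsiveness", {
  expect_equal(treat_step(0, 1, lv_default, eps = 0), 5)
  expect_equal(treat_step(50, 0.8, lv_default, eps = 0), 52)
  expect_equal(treat_step(100, 1, lv_default, eps = 0), 100)
  # clamping at the ceiling
  expect_equal(treat_step(99.9, 1, lv_default, eps = 1), 100)
})

test_that("the noise-free trajectory matches the closed form to 1e-9", {
  for (r in c(1, 0.8, 0.3, -0.5)) {
    h <- 20
    for (t in 1:60) {
      h <- treat_step(h, r, lv_default, eps = 0)
      expect_equal(h, min(100, max(0, treatment_trajectory(20, r, t))),
                   tolerance = 1e-9)
    }
  }
})

test_that("the noisy Monte-Carlo mean converges to the closed-form curve", {
  set.seed(404)
  n <- 1e4
  h <- numeric(n)
  for (t in 1:20) h <- treat_step(h, 1, lv_default)
  expected <- treatment_trajectory(0, 1, 20)
  se <- stats::sd(h) / sqrt(n)
  expect_lt(abs(mean(h) - expected), 3 * se)
})

test_that("denied treatment brings no systematic gain, no cost, and erodes trust", {
  lv <- default_levers(treatment_denial_rate = 1, arrival_rate = 5)
  run <- run_simulation(lv, n_steps = 120, seed = 19)
  expect_equal(run$final$cum_treatment_cost, 0)
  # health changes only by symmetric noise: population mean stays near entry
  entry_mean <- (lv$entry_health_min + lv$claim_threshold) / 2
  expect_lt(abs(run$final$mean_health - entry_mean), 5)
  # trust of treated (denied) workers collapses relative to a no-denial run
  run0 <- run_simulation(default_levers(treatment_denial_rate = 0,
                                        arrival_rate = 5),
                         n_steps = 120, seed = 19, attr_seed = 19)
  expect_lt(run$final$mean_trust, run0$final$mean_trust)
})

test_that("wage replacement is 80% of per-step salary, reduced pro-rata by fitness", {
  lv <- lv_default
  base <- accrue_wage_cost(55000, lv, fitness_credit = 0)
  expect_equal(base, round(0.80 * 55000 / lv$steps_per_year, 2))
  expect_equal(accrue_wage_cost(55000, lv, fitness_credit = 0.75),
               round(0.25 * 0.80 * 55000 / lv$steps_per_year, 2))
  expect_equal(accrue_wage_cost(55000, lv, fitness_credit = 1), 0)
  expect_error(accrue_wage_cost(55000, lv, fitness_credit = 1.2),
               "fitness_credit")
  # partial RTW strictly cheaper than full incapacity
  expect_lt(accrue_wage_cost(55000, lv, 0.4), base)
})

test_that("the RTW gate routes by health, policy and floor", {
  lv_n <- default_levers(rtw_policy = "neutral")
  lv_e <- default_levers(rtw_policy = "encourage", early_rtw_health_floor = 70)
  expect_equal(rtw_gate(96, lv_n), "to_rtw_pool")
  expect_equal(rtw_gate(95, lv_n), "to_rtw_pool")
  expect_equal(rtw_gate(80, lv_n), "stay_in_treatment")
  expect_equal(rtw_gate(80, lv_e), "to_employer_attempt")
  expect_equal(rtw_gate(69, lv_e), "stay_in_treatment")
  expect_equal(rtw_gate(96, lv_e), "to_rtw_pool")
  lv_d <- default_levers(rtw_policy = "discourage")
  expect_equal(rtw_gate(80, lv_d), "stay_in_treatment")
})

test_that("employer attempts compare readiness with the health shortfall", {
  expect_equal(attempt_employer_rtw(80, 20, lv_default), "partial_rtw")
  expect_equal(attempt_employer_rtw(80, 5, lv_default), "failed_rtw")
  expect_equal(attempt_employer_rtw(80, 5, lv_default,
                                    occ_rehab_available = TRUE),
               "partial_rtw_occ_rehab")
  expect_equal(attempt_employer_rtw(80, 15, lv_default), "partial_rtw")
})

test_that("occupational rehabilitation charges $10,000 once per supported worker", {
  r <- play_script(scenario_path("occ_rehab_partial.yaml"))
  expect_equal(r$state$sys_occ_rehab, 10000 * 100)  # cents
  expect_equal(r$state$n_partial_rtw, 1L)
  expect_equal(r$state$n_failed_rtw, 0L)
})

test_that("occ-rehab capacity bounds the number of supported workers per step", {
  lv <- default_levers(rtw_policy = "encourage", occ_rehab_enabled = TRUE,
                       occ_rehab_capacity = 1, arrival_rate = 0,
                       early_rtw_health_floor = 70)
  rng <- rng_source(c(
    # two workers in treatment: deny draws, eps draws, cost draws, then two
    # employer-readiness draws forced to zero readiness
    0.99, 0.99, 0.5, 0.5, 0.5, 0.5, 0.0, 0.0))
  state <- new_system_state(lv, rng = rng, trace = TRUE)
  inject_worker(state, make_worker(health = 80, responsiveness = 0.1,
                                   stage = "treatment"))
  inject_worker(state, make_worker(health = 80, responsiveness = 0.1,
                                   stage = "treatment"))
  advance(state, lv)
  expect_equal(state$n_partial_rtw, 1L)   # one bridged by occ rehab
  expect_equal(state$n_failed_rtw, 1L)    # the other fails
  expect_equal(state$sys_occ_rehab, 10000 * 100)
})

test_that("advertising raises employer readiness monotonically with saturation", {
  lv0 <- default_levers(advertising_spend = 0)
  expect_equal(readiness_with_advertising(25, lv0), 25)
  spends <- c(0, 100, 500, 1000, 5000, 1e6)
  r <- vapply(spends, function(s) {
    readiness_with_advertising(25, default_levers(advertising_spend = s))
  }, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 100))
  big <- readiness_with_advertising(90, default_levers(advertising_spend = 1e9))
  expect_equal(big, 100)
})

test_that("claims terminate only when duration strictly surpasses the maximum", {
  lv <- default_levers(max_claim_duration = 10)
  expect_false(check_termination(5, t = 15, lv))   # duration == limit
  expect_true(check_termination(5, t = 16, lv))    # limit + 1
  expect_false(check_termination(NA_integer_, t = 1e6, lv))
  lv_inf <- default_levers(max_claim_duration = Inf)
  expect_false(check_termination(1, t = 1e6, lv_inf))
})

test_that("system cost ledgers equal the sum of worker ledgers at every step", {
  run <- run_simulation(lv_small, n_steps = 250, seed = 33,
                        check_invariants = TRUE)  # asserted inside advance()
  st <- run$state
  p <- st$pop
  idx <- seq_len(st$n)
  expect_identical(st$sys_treatment, sum(p$led_treat[idx]))
  expect_identical(st$sys_wage, sum(p$led_wage[idx]))
  xfer <- idx[p$transferred[idx]]
  expect_identical(st$sys_medical, sum(p$led_gp[xfer] + p$led_ed[xfer]))
})

test_that("enabling occ-rehab does not increase failed RTWs (paired seeds)", {
  lv_off <- default_levers(rtw_policy = "encourage", occ_rehab_enabled = FALSE)
  lv_on <- default_levers(rtw_policy = "encourage", occ_rehab_enabled = TRUE)
  a <- run_simulation(lv_off, n_steps = 300, seed = 70, attr_seed = 70)
  b <- run_simulation(lv_on, n_steps = 300, seed = 70, attr_seed = 70)
  expect_lte(b$final$n_failed_rtw, a$final$n_failed_rtw)
  # and shifts the attempt mix toward partial returns
  mix_a <- a$final$n_partial_rtw /
    (a$final$n_partial_rtw + a$final$n_failed_rtw)
  mix_b <- b$final$n_partial_rtw /
    (b$final$n_partial_rtw + b$final$n_failed_rtw)
  expect_gt(mix_b, mix_a)
})
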