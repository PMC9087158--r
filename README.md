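# worksim

An agent-based, discrete-time simulator of a no-fault workers' compensation
scheme, for policy analysts and health-system modellers who want to explore
how claims-management levers interact before anything touches a real
scheme. Synthetic injured workers flow through triage (GP or emergency
department), claim lodgement and adjudication, disputes, funded treatment
and return to work (RTW), while the simulator tracks each worker's health,
trust, satisfaction and costs, and the scheme's aggregate monitors. A
factorial experiment runner compares policy conditions with paired random
seeds.

Time is an uncalibrated unit and costs are uncalibrated dollars: the tool
compares the *direction* of policy effects, not magnitudes.

## The model in brief

Workers carry health, trust, satisfaction and fight appetite on 100-point
scales, a treatment-responsiveness multiplier r ∈ [−1, 1], and a
positively skewed salary (lognormal, mean $55k, sd $10k). Each time-step:

* ~10 workers arrive; half see a GP (cost ~ N(100, 20)), half an emergency
  ward ($1000); below-threshold workers (health < 95) are referred to
  claim lodgement, though GPs err with probability 0.1.
* Claims queue FIFO against an administrative capacity; acceptance is
  Bernoulli by injury type — 90% acute physical, 60% chronic physical,
  40% mental health. Denied workers lose trust and dispute with
  probability (fight/100)·(1 − trust/100).
* Treated health follows `h' = h + 0.05·(100 − h)·r + ε`, ε ~ U[−1, 1], so
  recovery is fast early and slow near full health; each service costs
  ~ N(100, 20). Wage replacement accrues at 80% of per-step salary,
  reduced pro-rata during partial RTW (a worker 75% fit costs
  25% × 0.8 × salary).
* At health ≥ 95 a worker returns to work fully. Under an `encourage`
  policy, workers at health ≥ 70 attempt an early return through their
  employer: employer readiness must cover the health shortfall, optionally
  bridged by occupational rehabilitation at $10,000 per worker; otherwise
  the attempt is a failed RTW.
* Benefits terminate when a claim's duration strictly surpasses the
  maximum (default 1000 steps).

Every lever (about thirty — thresholds, rates, capacities, costs, the RTW
policy, advertising, dispute settings, arrival and entry distributions) is
a field of `default_levers()` and of the YAML config schema; run
`str(default_levers())` for the full inventory with defaults, and see the
methods vignette (`vignettes/worksim-model.Rmd`) for what each means and
why its default is what it is.

## Worked example

```r
library(worksim)
run <- run_simulation(default_levers(), n_steps = 500, seed = 42)
print(run)
#> <worksim run: 500 steps, seed 42>
#>   final: 427 in system; mean health 80.0, trust 61.9, satisfaction 71.4
#>   RTW full/partial/failed: 2845/0/0; disputes 2115; terminated 0
#>   cum cost $175108561.64 (treatment 16485949.54, wage 156863618.20, medical 1758993.90, occ rehab 0.00)
#>   mean claim duration at exit: 56.5 steps
```

After 500 steps, 427 workers are inside the scheme (most in treatment),
2,845 have returned to work at full capacity, and 2,115 disputes have been
lodged. The wage-replacement bill dwarfs treatment costs — the scheme pays
80% of salary for every step a claim stays open, which is why claim
duration drives total cost. Under the default `neutral` RTW policy there
are no partial or failed RTWs: those appear under `encourage`:

```r
run_e <- run_simulation(default_levers(rtw_policy = "encourage",
                                       occ_rehab_enabled = TRUE),
                        n_steps = 500, seed = 42)
```

The six-condition policy experiment (RTW policy × occupational
rehabilitation, 30 paired replicates of 2000 steps each):

```r
results <- run_matrix(default_matrix(base_seed = 17))
print(results)
```

A per-step monitor CSV is written with `write_timeseries(run$series,
"run.csv")`. Shell front ends live in `inst/scripts/`: `worksim run
--config cfg.yaml --out run.csv`, `worksim experiment --reps 30 --out
results.csv`, and `plot_results.R` draws the condition bar charts from the
results CSV.

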