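---
title: "The worksim model: pathways, psychology and policy levers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The worksim model: pathways, psychology and policy levers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worksim)
```

worksim is a discrete-time, agent-based simulator of a no-fault workers'
compensation scheme. Injured workers enter the system, are triaged by a GP
or an emergency department, lodge claims against a capacity-limited
administrative function, receive (or are denied) funded treatment, may
dispute unfavourable decisions, and eventually return to work — fully,
partially through their employer, or not at all before their benefits are
terminated. The scheme operator steers the system through policy levers:
acceptance rates, processing and treatment capacities, wage replacement,
the return-to-work (RTW) policy, occupational rehabilitation, advertising
and the maximum claim duration.

Time is a deliberately uncalibrated unit. Costs are accounted in dollars
(internally in integer cents, so conservation identities hold exactly) but
are not calibrated to any real scheme; the tool compares the *direction* of
policy effects, never their absolute magnitude.

## The worker

Each worker carries:

* **health**, **trust**, **satisfaction** and **fight appetite** on
  100-point scales, always clamped to $[0, 100]$;
* a fixed **responsiveness** multiplier in $[-1, 1]$ scaling treatment
  effectiveness (negative responders deteriorate under treatment);
* an annual **salary**, positively skewed, mean \$55,000, sd \$10,000;
* an **expected claim-processing wait** (mean 35 steps);
* an **injury type**: acute physical, chronic physical or mental health;
* a bounded **event memory** (up to 300 entries) of the discrete
  psychological events that befell them;
* per-category **cost ledgers** (GP, emergency, treatment, wage).

Entry distributions the narrative leaves open are fixed as model
definition: health uniform on $[20, \text{claim threshold})$ so every
entrant is plausibly claim-eligible; trust and satisfaction uniform on
$[50, 100]$; fight uniform on $[0, 100]$; responsiveness truncated normal
on $[-1, 1]$ with mean 0.8 (matching the worked example of a 0.8
multiplier) and sd 0.2; salary lognormal re-parameterized to the target
mean and sd — the simplest positively skewed two-parameter family; the
expected wait normal(35, 10) floored at one step. All are levers.

## The pathway

`advance()` executes one time-step in a fixed phase order, which is part of
the model definition (the narrative does not specify intra-step ordering;
this order follows the state chart left to right):

1. **Spawn** — `arrival_rate` workers (default 10/step) enter; with
   arrival variation enabled the rate performs a ±1 random walk every 50
   steps. An optional mass-incident toggle injects a one-off cohort.
2. **Triage** — 50% (a lever) present to a GP (cost ~ N(100, 20), censored
   at 0, on the worker's ledger), the rest to emergency (fixed \$1000).
   The GP refers below-threshold workers to claim lodgement, the rest back
   to the workplace — but matches the true comparison only with
   probability `gp_accuracy` (default 0.9). The emergency assessment is
   error-free: the narrative attributes misdiagnosis only to GPs.
3. **Workplace re-check** — health drifts up by a *small waitlist effect*,
   $\max(0, N(0.01, 0.1))$ per step; workers still at or below the
   threshold return to lodgement and lose trust; the rest leave the scheme.
4. **Adjudication** — up to `claims_processing_capacity` claims per step
   (FIFO; a claim always waits at least one step, so "held there" is
   meaningful). Acceptance is Bernoulli with injury-type rates 0.90 / 0.60
   / 0.40. On acceptance the claim clock starts and the worker's GP/ED
   costs transfer to the system ledger — never on denial, so the medical
   costs of never-accepted workers stay private to the worker forever. On
   denial the worker loses trust and either disputes or exits.
5. **Dispute resolution** — a dispute occupies `dispute_duration` steps
   (default 5; the narrative says trust and satisfaction erode "over the
   period" in dispute, which requires disputes to take time) and succeeds
   with `dispute_success_rate` (default 0.5). Successful claim disputes
   rejoin the back of the lodgement queue — this can repeat many times;
   failed ones exit. Treatment disputes return toward treatment on success
   and re-enter through the accepted area on failure.
6. **Treatment** — admission up to `treatment_capacity`; each treated step
   closes `treatment_gain_rate` (5%) of the gap to 100, scaled by
   responsiveness, plus uniform noise on $[-1, 1]$; each service costs
   ~ N(100, 20) to worker and system. Treatment is denied with probability
   `treatment_denial_rate` (default 0.05): no systematic gain, no cost, a
   trust penalty and a possible dispute.
7. **Return to work** — at or above the claim threshold (default 95) a
   worker makes a full RTW and leaves. Under the `encourage` policy,
   workers at or above `early_rtw_health_floor` (default 70) attempt an
   employer return: if employer readiness (uniform on
   $[0, \texttt{employer\_readiness\_max}]$, default max 30, plus a
   saturating advertising gain $50\,s/(s+1000)$) covers the health
   shortfall, the worker makes a partial RTW; otherwise occupational
   rehabilitation — when enabled and within its per-step capacity — bridges
   the gap at \$10,000 per supported worker, and failing that the attempt
   is a *failed RTW* and the worker stays in treatment. Partial returners
   recover at the waitlist drift rate (they are at work, not in care) and
   convert to full RTW at the threshold. `neutral` does no employer
   routing, and `discourage` additionally keeps workers in treatment until
   the full threshold; in this engine the two coincide behaviourally.
8. **Termination** — benefits stop when the claim duration strictly
   surpasses `max_claim_duration` (default 1000; rare but reachable in a
   2000-step run).
9. **Wage accrual** — every accepted claim off full work accrues
   $(1 - \text{fitness}) \times 0.8 \times \text{salary}/\texttt{steps\_per\_year}$,
   with fitness 0 off work and health/100 during partial RTW (a worker 75%
   fit costs 25% of the 80% entitlement). `steps_per_year` is 50 — time is
   uncalibrated; this makes a 2000-step run a plausible multi-year horizon.
10. **Psychology** — per-step decays: −1 trust and satisfaction per step in
    dispute, −1 trust per queued step beyond the worker's expected wait.
    Discrete events (denials, send-backs, dispute outcomes) apply the
    configurable delta table and are written to the worker's memory;
    the per-step decay states are continuous conditions, not events, and
    are not logged. The dispute decision is
    $p = (\text{fight}/100)(1 - \text{trust}/100)$ — the minimal form that
    rises with fight appetite and falls with trust; exponent hooks exist.

All randomness flows through a single uniform-draw gate and inverse-CDF
transforms, so a scripted random source (a fixed queue of uniforms) replays
any trajectory through the production engine exactly; the shipped YAML
scenarios under the test tree exercise every transition of the state chart
this way.

## Numerical choices

* Cost ledgers are integer cents; system-versus-worker ledger conservation
  is asserted as exact integer equality, not within a float tolerance.
* Cost draws use a normal censored at zero; at mean 100, sd 20 the censored
  mass (~3e-7) is negligible, and the inverse-CDF form keeps draws
  scriptable.
* The noise-free treated-health trajectory admits the closed form
  $h_t = 100 - (100 - h_0)(1 - 0.05\,r)^t$, used as an oracle at tolerance
  1e-9; with noise on, Monte-Carlo means over 10,000 workers match it
  within three standard errors.
* Means over empty groups are reported as missing (`NA`), never zero.
* Ties and boundaries: a duration exactly at the maximum is *not*
  terminated ("surpassed" is strict); health exactly at the threshold *is*
  a full RTW ("equal to or above").

## Calibration of the six-condition comparison

The default experiment crosses the RTW policy (discourage / neutral /
encourage) with occupational rehabilitation (off / on), 30 replicates of
2000 steps per condition, replicate seeds paired across conditions and
entrant attributes drawn from a counter-based substream so every condition
faces the identical entrant population.

The qualitative pattern this comparison is expected to reproduce — recovery
promoted in a treatment setting yields the lowest in-system counts and exit
durations, active employer encouragement plus occupational rehabilitation
the highest, with total costs following durations — is a property of the
model *regime*, not of any single equation. Three defaults place the model
in that regime, and are documented here as deliberate calibration:

* responsiveness centred at 0.8 — treatment-setting recovery is fast for
  the typical worker, so the wage bill is not dominated by a slow tail;
* a genuinely small waitlist drift (mean per-step gain ≈ 0.04 health
  units) — a partial returner recovers much more slowly at work than in
  care, which is the friction behind the poor performance of early
  employer returns;
* modest employer readiness (uniform up to 30 against shortfalls of up to
  25) — encouragement produces a high proportion of failed RTW attempts,
  and occupational rehabilitation converts them into early, slow partial
  returns.

With a fast at-work drift or generous employers the ordering genuinely
reverses (early returns then rescue poorly responding workers from long
claims); both regimes are reachable through the levers, and the comparison
is therefore tested only at the shipped defaults.

## What the synthetic population does and does not show

The generator emulates a stationary flow of independent synthetic workers
with uncorrelated attributes. It does not model demographic covariates,
injury-type-specific entry health, relapse at work, legal costs of
disputes, correlated shocks beyond the optional capacity/mass-incident
toggles, or any real scheme's finances. Passing tests demonstrate internal
consistency and the stated emergent properties of this model — not
predictions about any real compensation system.

## Problem sizes used by the tests

Distribution echoes use 10,000–100,000 draws (binomial three-sigma
intervals); engine-level properties run 100–400-step systems; the
conservation suite re-checks every step of one full 2000-step default run;
the policy comparison runs the full 30 × 6 × 2000 design. These sizes keep
the whole suite in the tens of minutes on a single core while leaving
Monte-Carlo error far below every asserted margin.

## Known limitations

* `discourage` and `neutral` coincide; the three-way policy is kept for
  interface fidelity, and the matrix collapses to four distinct dynamics.
* Worker memory influences nothing yet: the delta table acts directly on
  trust/satisfaction, and memory is an observable log (the mechanism by
  which memory feeds behaviour is not defined by the model narrative).
* Satisfaction is tracked as an outcome only; behavioural feedback runs
  through trust alone.
* Absolute costs, durations and counts are uncalibrated by design.
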