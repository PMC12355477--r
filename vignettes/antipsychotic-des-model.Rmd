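---
title: "A discrete event simulation of antipsychotic treatment pathways in first-episode schizophrenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete event simulation of antipsychotic treatment pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schizosim)
```

## Why a discrete event simulation

Cohort (Markov) models force disease history into a fixed cycle length and
a homogeneous cohort. Antipsychotic choice in first-episode schizophrenia
is a poor fit for both: relapse risk differs across patients (adherence,
metabolic profile), treatment sequences branch at patient level, and the
cardio-metabolic consequences of antipsychotics act through continuous
individual risk profiles. `schizosim` therefore simulates individual
patients in continuous time: each patient carries a time-varying state
(disease status, treatment line, metabolic profile, comorbidity history),
candidate events carry sampled times, the earliest event fires, state is
updated, and only clocks whose hazards changed are regenerated. A
trajectory ends at death or the time horizon (default ten years).

## Events and pathway rules

Eight event types drive the simulation: relapse, remission,
discontinuation (recurrent), and tardive dyskinesia, first CHD, first
stroke, diabetes onset, death (at most once each).

* **Relapse.** Exponential. The untreated hazard is
  `-log(1 - p_relapse)` with `p_relapse` the annual relapse probability
  under no treatment (illustrative default 0.45/year). On treatment the
  hazard is multiplied by `1 + (RR - 1) * w`: `RR` is the drug's relapse
  risk ratio and `w` the adherence weight — 1 for full adherence (the full
  treatment effect), 0 for non-adherence (untreated hazard), 0.5 for
  partial adherence by default. Long-acting injectables impose `w = 1`
  regardless of the patient's adherence category. No relapse can be
  scheduled during an ongoing episode.
* **Remission.** Deterministic, `remission_duration` (default 0.5 years)
  after the relapse; the relapse clock restarts at remission.
* **Switching.** At relapse the patient switches line with probability
  `switch_prob_after_relapse` (default 0.5). Lines run first →
  second → clozapine; clozapine is absorbing. Clozapine is reached at the
  first switch after two consecutive failures, where *failure = relapse*.
  Two pathway questions are genuinely open and are exposed as documented
  behavioural switches:
  * `relapse_counts_without_switch` (default `TRUE`): a relapse that does
    not trigger a switch still counts toward the two-failure criterion.
    The default reads "two consecutive failures" as counting relapses,
    not switches.
  * `restart_same_treatment_after_relapse` (default `TRUE`): a patient who
    had discontinued, relapses, and does not switch restarts the
    current-line drug at remission. The alternative (remaining untreated
    indefinitely) would conflate treatment lines with no-treatment arms.
* **Discontinuation.** Exponential at `-log(1 - p_disc)` per treatment
  episode. Discontinuation removes the drug's metabolic shifts, stops
  drug-cost accrual, suspends the tardive dyskinesia clock and raises the
  relapse hazard to the untreated level (the relapse clock is redrawn).
  Restarting a treatment starts a fresh episode, with a new
  discontinuation clock and fresh short-term side-effect draws.
* **Tardive dyskinesia.** Exponential at `-log(1 - p_TD)` while on
  treatment; at most once per patient; permanent utility decrement and
  chronic management cost. Suspending the clock while off treatment and
  redrawing on restart is distribution-preserving because the exponential
  is memoryless.
* **Side-effects at treatment start.** Each short-term side-effect (acute
  EPS, sedation, sexual dysfunction, weight gain; agranulocytosis for
  clozapine only) is drawn Bernoulli at initiation, is active for
  `short_term_se_duration` (default 0.25 years) with its decrement, and
  incurs a one-off management cost. Agranulocytosis triggers an immediate
  case-fatality check. Switching *because of* side-effects is deliberately
  not modelled directly; it is absorbed into all-cause discontinuation.

## Cardio-metabolic risk and mortality

Risk equations are configuration data, not code. Each outcome (CHD,
stroke, diabetes) carries a named coefficient vector over patient
covariates (optionally log-transformed) in one of two published
functional forms: Cox-type, `risk = 1 - S0 ^ exp(lp - mean_lp)`, or
logistic, `risk = plogis(intercept + lp)`, over a stated score horizon
(10 years for CHD/stroke, 8 for diabetes in the shipped set). The horizon
risk becomes an event time through a constant-hazard assumption,
`rate = -log(1 - risk) / horizon` — the standard convention when a score
gives only a horizon probability.

Hazards respond to treatment because metabolic shifts enter the
covariates: clocks for not-yet-occurred outcomes are recomputed at every
event that changes covariates (treatment start/stop, diabetes onset,
CHD/stroke occurrence) and redrawn only if the rate actually changed —
redrawing an unchanged exponential clock would be distribution-neutral
but would desynchronise common random numbers. Covariate age is the
current (continuous) age at the moment of rescheduling; between events
the hazard is held constant, a piecewise-constant approximation whose
error is bounded by the event density and is negligible over a ten-year
horizon with annual-scale event rates. Diabetes onset sets the diabetes
covariate in the CHD and stroke equations thereafter. Patients with a
prior condition at baseline cannot experience the corresponding *first*
event and carry its decrement and chronic cost from entry.

Background mortality is an inverse-transform sample from the life-table
survival curve with the schizophrenia standardised mortality ratio
applied as `q' = 1 - (1 - q)^SMR` (constant hazard within each year of
age); death is certain by the table's maximum age. The shipped life table
(`inst/extdata/life_table_synthetic_uk.csv`) is synthetic — a smooth
Gompertz-plus-constant curve of UK-like magnitude — and is replaceable by
a national table in the same three-column CSV format.

## Outcomes

Utilities: a state weight (`u_stable`, default 0.88; `u_relapse`, 0.60)
minus additive decrements for active conditions, floored at zero. The
combination rule is not settled in the literature; additive-with-floor is
the package default, and when the floor binds the loss is attributed to
conditions pro rata so the outcome decomposition still sums exactly. The
decomposition separates years in stable state, QALYs excluding
side-effect losses, QALY losses from cardio-metabolic conditions
(post-CHD, post-stroke, diabetes), and losses from other side-effects
(EPS, weight gain, sedation, sexual dysfunction, tardive dyskinesia, and
agranulocytosis).

Costs (2020£, health-service perspective): drug acquisition while on
treatment, background care, relapse episodes, side-effect management,
acute and chronic cardio-metabolic care, and a death cost. The relapse
cost carries a documented dialect flag because either convention appears
in practice: `per_episode` (default) lumps the episode cost at the
relapse event with background care accruing throughout; `per_year`
replaces the background rate with a relapse-state rate and adds no lump.

Discounting is continuous-time at an annual rate `r` (default 0.035):
`weight(t0, t1) = ((1+r)^-t0 - (1+r)^-t1) / log(1+r)`, the exact integral
of the discount factor. DES event times are continuous, so annual-bucket
discounting would add cycle artefacts that the closed form avoids; event
lumps are discounted at the factor of their event time.

## The synthetic cohort generator

The model is populated from summary-level baseline statistics, not
patient records. Continuous characteristics (age and the six metabolic
markers) are drawn from truncated normals via inverse CDF at the
configured mean, SD and plausibility bounds; categorical characteristics
(sex, smoking, alcohol, adherence) from their configured shares; history
flags (prior CHD/stroke/diabetes, antihypertensive treatment) as
Bernoulli. Markers are independent by default — matching what
summary-level sources support — with an optional Gaussian copula
(`correlate_metabolics()`) that preserves the truncated-normal marginals
when a dependence structure is available.

What this emulates, and what it does not: generated cohorts converge to
the configured moments and shares (property-tested against quadrature and
binomial oracles), but they cannot reproduce joint structure the summary
statistics do not carry — real metabolic covariance, adherence–smoking
association, or heavy tails. Tests passing on synthetic cohorts therefore
validate the *machinery*, not the epidemiology of any real population.

## Uncertainty analyses

* **PSA.** Each uncertain quantity carries a distribution in the config
  (`beta` for probabilities and utilities, `gamma` for costs, `lognormal`
  for ratios, `normal` otherwise, `fixed` to pin) — standard
  health-economic convention. A draw resamples all of them independently,
  revalidates, reruns the (reduced-size) simulation and ranks by NMB;
  rank frequencies over draws form a treatment × rank matrix that is
  doubly stochastic by construction. By default every draw reuses the
  same run seed (common random numbers across draws), so an all-fixed
  uncertainty map reproduces the deterministic ranking exactly and
  parameter uncertainty is not blurred by re-simulation noise;
  `independent_runs = TRUE` restores fully independent sampling.
* **DSA.** One parameter at a time at its 2.5th/97.5th PSA percentiles
  (±20% for fixed quantities), both arms rerun under common random
  numbers, tornado-ordered by the swing in incremental NMB. Under common
  random numbers a perturbation that cannot touch the event process
  (e.g. a drug price) leaves incremental QALYs exactly unchanged — a
  property the test suite asserts exactly, not approximately.
* **Scenarios.** Declared axes only: horizon, discount rate, treatment
  subset, and starting line. `starting_line = 2` evaluates the drugs as
  second-line treatment: patients enter with one prior failure recorded,
  so their next switch goes straight to clozapine; since the sequence's
  second slot is then unreachable, one sequence per drug is simulated.

## Random numbers and reproducibility

Every stochastic component draws from a substream keyed by a
Lehmer-mixed `(master_seed, patient, replication, purpose)` tuple. The
cohort and each patient's background death time use sequence-independent
substreams, and the event loop consumes a fixed number of uniforms per
decision point, so with `common_random_numbers: true` (default) two
treatment sequences share baseline profiles, death times and all event
draws up to the first point where their pathways diverge — the classic
variance-reduction setup for pairwise comparisons. Setting it to `false`
keys the streams by sequence as well, giving fully independent arms.
Identical seeds give byte-identical outputs end to end, including CSV
exports; every CLI run writes a `manifest.json` sufficient to reproduce
it.

## Numerical choices

* Event ties are broken by a fixed priority: death > CHD > stroke >
  diabetes > relapse > remission > discontinuation > tardive dyskinesia.
  Death first prevents post-mortem events at exact ties; the rest is an
  arbitrary but frozen order.
* `risk = 0` schedules no event (`Inf`); `risk = 1` is rejected as
  degenerate rather than silently scheduling an immediate event.
* A guard of 10,000 events per trajectory (configurable) turns parameter
  pathologies (e.g. zero remission duration with near-certain relapse)
  into a diagnostic error instead of a hang.
* Utility floor at zero with pro-rata loss attribution (above).
* PSA draws outside a distribution's support are rejected and redrawn
  (bounded retries), and the drawn set is revalidated in full.

## Parameter provenance and problem sizes

The shipped `illustrative_uk.yaml` is labelled non-authoritative
throughout: values were chosen once to be realistic in magnitude and
ordering for a UK first-episode evaluation (relapse risk ratios on the
scale reported by recent relapse-prevention network meta-analyses,
2020-era annual drug costs, commonly used state utilities,
health-service unit costs, Framingham-style equation shapes) and are not
revisited against outputs. Reproducing any specific published analysis
requires replacing the parameter blocks with that analysis's source
values in the same schema.

Default simulation settings follow the standard design for this problem:
1000 patients × 100 replications per sequence, ten-year horizon, 3.5%
annual discounting, WTP grid £0–£100,000/QALY, 1000 PSA draws. The test
suite and the acceptance script run the same machinery at desk scale —
tens of patients and a handful of replications per sequence, a few
thousand Monte-Carlo draws for sampler checks, 10⁵ trajectories for the
invariant scan — sizes chosen so the whole suite runs in minutes on one
core while keeping Monte-Carlo error well inside the asserted
tolerances. Oracles are independent implementations: quadrature for
truncated-normal moments, closed-form exponential and renewal results, a
fine-grid (daily) deterministic discretisation of the relapse–remission
process for engine-level QALY and relapse-count checks, and a
straight-line re-implementation of the risk equations.

## Known limitations

* The risk equations are US-derived Framingham-style scores; no
  UK-recalibrated cardio-metabolic model for severe mental illness is
  bundled. Coefficients are config, so such a model can be dropped in.
* First events only: recurrent CHD/stroke and post-event survival
  modelling beyond a chronic state are out of scope.
* Side-effect-driven switching is only implicit (via all-cause
  discontinuation), and metabolic shifts vanish immediately at
  discontinuation although some (e.g. BMI) persist in reality.
* The synthetic cohort cannot carry joint structure absent from its
  summary-level inputs (above).
* Utility decrement combination (additive with floor) and the relapse
  cost dialect are conventions, flagged as switches rather than settled
  facts.
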