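# schizosim

A patient-level **discrete event simulation (DES)** model for the
cost-utility analysis of antipsychotic treatment sequences in
first-episode schizophrenia, written for health economists and
psychiatric-services researchers who need a transparent, configurable
alternative to cohort (Markov) models.

## The model in brief

Patients enter the model in a stable state on a first-line antipsychotic
and move through events in continuous time: relapse, remission, all-cause
treatment discontinuation, tardive dyskinesia, first coronary heart disease
(CHD) event, first stroke, diabetes onset, and death. Relapse, remission
and discontinuation can recur; the other events occur at most once.

* **Event times.** Waiting times are exponential. An annual probability
  *p* is converted to a constant hazard *λ = −log(1 − p)*. On treatment
  the relapse hazard is multiplied by *1 + (RR_t − 1)·w*, where *RR_t* is
  the treatment's relapse risk ratio versus no treatment and *w ∈ [0, 1]*
  the patient's adherence weight (long-acting injectables force *w = 1*).
* **Treatment sequence.** At each relapse the patient switches line with
  probability *π* (default 0.5). The second line is any not-yet-tried
  antipsychotic; the third and last line is always clozapine, reached at
  the first switch after two consecutive failures. With *n* first-line
  candidates the comparison runs all *n(n−1)* sequences (90 for the ten
  shipped candidates) and aggregates per first-line drug as the equally
  weighted mean over its sequences.
* **Cardio-metabolic risk.** While on treatment, each drug shifts the
  metabolic profile (BMI, total cholesterol, HDL-C, triglyceride, fasting
  glucose, SBP). Framingham-style risk equations map the current profile
  to a horizon risk for CHD, stroke and diabetes, converted to an event
  time by *rate = −log(1 − risk)/horizon*; affected clocks are redrawn
  whenever covariates change. Background mortality comes from a life table
  with a standardised mortality ratio applied as *q′ = 1 − (1 − q)^SMR*;
  agranulocytosis (clozapine only), CHD and stroke carry acute case
  fatality.
* **Outcomes.** Utilities are state weights (stable/relapse) minus
  additive decrements for active conditions, floored at 0; costs cover
  drug acquisition, background care, relapse episodes, side-effect
  management, cardio-metabolic events and chronic care, and death. Both
  are discounted in continuous time,
  *w(t₀, t₁) = ((1+r)^(−t₀) − (1+r)^(−t₁))/log(1+r)*.
* **Decision metrics.** Net monetary benefit *NMB = QALYs·λ_WTP − costs*
  ranks first-line drugs across willingness-to-pay thresholds; the package
  also produces pairwise ICERs with dominance labels, probabilistic
  sensitivity analysis (PSA) rank-probability matrices, one-way
  deterministic sensitivity (tornado) tables and scenario analyses
  (horizon, discount rate, second-line use).

All parameters travel in a single documented YAML file
(`inst/params/illustrative_uk.yaml` shows every field). **The shipped
parameter set is illustrative, not authoritative**: values are realistic
in magnitude and ordering for a UK evaluation but are not those of any
published analysis; drop in your own estimates in the same schema to
reproduce a specific study.

## Worked example

```r
library(schizosim)
cfg <- system.file("params", "illustrative_uk.yaml", package = "schizosim")
p   <- load_parameter_set(cfg)
res <- run_base_case(p, seed = 1, n_patients = 50, n_reps = 2)  # desk scale
rank_treatments(res, 20000)
```

```
          treatment   qalys   cost      nmb rank
1        olanzapine 6.84231 140170 -3323.65    1
2       amisulpride 6.84506 140766 -3864.75    2
3   risperidone_lai 6.86330 141880 -4614.29    3
4      aripiprazole 6.84170 141989 -5155.02    4
5       risperidone 6.83551 141943 -5233.04    5
6  paliperidone_lai 6.85686 142538 -5401.06    6
7  aripiprazole_lai 6.87266 143602 -6148.54    7
8       cariprazine 6.84459 143843 -6950.80    8
9        quetiapine 6.82631 143527 -7001.11    9
10       lurasidone 6.82796 145129 -8569.87   10
```

Each row is one first-line antipsychotic averaged over its nine
sequences: discounted QALYs over ten years, discounted cost (2020£, NHS
perspective) and net monetary benefit at £20,000/QALY; `res` itself holds
the full outcome decomposition (years in stable state, QALYs excluding
side-effect losses, QALY losses from cardio-metabolic conditions and from
other side-effects, cost components) with Monte-Carlo standard errors. At
this illustrative desk scale the low-cost/low-relapse drugs (olanzapine,
amisulpride, risperidone-LAI) head the ranking and the expensive
newer agents trail — the NMB spread between adjacent ranks is of the same
order as the Monte-Carlo error, so desk-scale ranks of neighbours should
not be over-read; increase `n_patients`/`n_reps` for decision-grade runs.

A command-line interface wraps the same functions:

```sh
schizosim simulate --config params.yaml --seed 1 --outdir out/
schizosim psa --config params.yaml --n-draws 100 --outdir out/
schizosim dsa --config params.yaml --pair amisulpride,olanzapine --outdir out/
```

Every output directory receives a `manifest.json` (command, config hash,
seed, package version) from which the run can be reproduced exactly.

## Further reading

The methods vignette (`vignettes/antipsychotic-des-model.Rmd`) documents
the model assumptions, every tunable parameter with units and defaults,
the synthetic-cohort generator and its limits, numerical choices
(tie-breaks, clock regeneration, discounting) and known limitations.
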