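# Minimal three-treatment configuration for fast smoke tests and examples.
# Same schema as illustrative_uk.yaml; values are arbitrary but valid.
schema_version: 1

treatments:
  alpha:
    route: oral
    relapse_risk_ratio: 0.5
    annual_discontinuation_prob: 0.3
    annual_td_prob: 0.01
    metabolic_deltas: {bmi: 2.0, glucose: 0.2}
    short_term_se_probs: {sedation: 0.2, weight_gain: 0.2}
    annual_drug_cost: 100
  beta:
    route: LAI
    relapse_risk_ratio: 0.6
    annual_discontinuation_prob: 0.25
    annual_td_prob: 0.02
    metabolic_deltas: {bmi: 0.5}
    short_term_se_probs: {acute_eps: 0.1}
    annual_drug_cost: 1500
  clozapine:
    route: oral
    relapse_risk_ratio: 0.4
    annual_discontinuation_prob: 0.2
    annual_td_prob: 0.005
    metabolic_deltas: {bmi: 3.0, glucose: 0.3}
    short_term_se_probs: {sedation: 0.3, agranulocytosis: 0.01}
    annual_drug_cost: 250
    is_clozapine: true

epidemiology:
  annual_relapse_prob_no_treatment: 0.45
  remission_duration: 0.5
  switch_prob_after_relapse: 0.5
  adherence_shares: {full: 0.6, partial: 0.2, none: 0.2}
  adherence_effect_weights: {full: 1.0, partial: 0.5, none: 0.0}
  smr_schizophrenia: 2.5
  case_fatality: {agranulocytosis: 0.05, chd: 0.25, stroke: 0.2}

utilities:
  u_stable: 0.88
  u_relapse: 0.60
  decrements:
    acute_eps: 0.07
    sedation: 0.04
    sexual_dysfunction: 0.04
    weight_gain: 0.04
    tardive_dyskinesia: 0.03
    agranulocytosis: 0.10
    post_chd: 0.12
    post_stroke: 0.15
    diabetes: 0.07
  short_term_se_duration: 0.25

costs:
  annual_stable_care_cost: 10000
  annual_relapse_episode_cost: 17000
  per_event_acute_cost: {chd: 5000, stroke: 12000, agranulocytosis: 5000, sedation: 150, weight_gain: 150}
  annual_chronic_cost: {post_chd: 600, post_stroke: 3000, diabetes: 1500, tardive_dyskinesia: 400}
  death_cost: 5000
  currency_year: 2020

risk_models:
  diabetes:
    form: logistic
    variant: illustrative-framingham-style-8y
    horizon: 8
    intercept: -10.4
    terms:
      - {covariate: glucose, coef: 0.8}
      - {covariate: bmi, coef: 0.07}
      - {covariate: age, coef: 0.03}

life_table_csv: ../extdata/life_table_synthetic_uk.csv

baseline:
  continuous:
    age:        {mean: 26.0, sd: 7.0,  lower: 16.0, upper: 60.0}
    bmi:        {mean: 24.5, sd: 4.5,  lower: 15.0, upper: 50.0}
    total_chol: {mean: 4.8,  sd: 1.0,  lower: 2.5,  upper: 10.0}
    hdl:        {mean: 1.4,  sd: 0.35, lower: 0.5,  upper: 3.5}
    trig:       {mean: 1.3,  sd: 0.8,  lower: 0.3,  upper: 8.0}
    glucose:    {mean: 5.0,  sd: 0.7,  lower: 3.0,  upper: 15.0}
    sbp:        {mean: 120.0, sd: 13.0, lower: 85.0, upper: 200.0}
  categorical:
    sex: {male: 0.6, female: 0.4}
    smoking: {current: 0.5, never: 0.5}
    alcohol: {none: 0.3, moderate: 0.6, high: 0.1}
    adherence: {full: 0.6, partial: 0.2, none: 0.2}
  binary:
    prior_chd: 0.0
    prior_stroke: 0.0
    prior_diabetes: 0.02
    antihypertensive: 0.02

sim:
  n_patients: 20
  n_replications: 2
  horizon: 10
  annual_discount_rate: 0.035
  wtp_grid: [0, 20000, 100000]
  base_wtp: 20000
  n_psa_draws: 10
  psa_n_patients: 10
  psa_n_reps: 1
  master_seed: 42

uncertainty:
  - {path: epidemiology/annual_relapse_prob_no_treatment, dist: beta, shape1: 45, shape2: 55}
  - {path: treatments/alpha/relapse_risk_ratio, dist: lognormal, meanlog: -0.6931472, sdlog: 0.15}
  - {path: treatments/alpha/annual_drug_cost, dist: gamma, shape: 25, scale: 4}
  - {path: utilities/u_relapse, dist: beta, shape1: 60, shape2: 40}
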