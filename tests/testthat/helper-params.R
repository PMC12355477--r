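# Programmatic fixtures: small parameter sets built in code.

# flat inline life table: constant annual death probability, q = 1 at max age
flat_life_table <- function(q = 0.002, age_min = 15, age_max = 100) {
  ages <- age_min:age_max
  qq <- rep(q, length(ages))
  qq[length(qq)] <- 1
  list(age = ages, male = qq, female = qq)
}

# Base three-treatment configuration as a plain list (same schema as the
# YAML files); tests modify it and call parameter_set().
test_param_list <- function() {
  list(
    schema_version = 1,
    treatments = list(
      alpha = list(route = "oral", relapse_risk_ratio = 0.5,
                   annual_discontinuation_prob = 0.3, annual_td_prob = 0.01,
                   metabolic_deltas = list(bmi = 2, glucose = 0.2),
                   short_term_se_probs = list(sedation = 0.2, weight_gain = 0.2),
                   annual_drug_cost = 100),
      beta = list(route = "LAI", relapse_risk_ratio = 0.6,
                  annual_discontinuation_prob = 0.25, annual_td_prob = 0.02,
                  metabolic_deltas = list(bmi = 0.5),
                  short_term_se_probs = list(acute_eps = 0.1),
                  annual_drug_cost = 1500),
      clozapine = list(route = "oral", relapse_risk_ratio = 0.4,
                       annual_discontinuation_prob = 0.2, annual_td_prob = 0.005,
                       metabolic_deltas = list(bmi = 3, glucose = 0.3),
                       short_term_se_probs = list(sedation = 0.3,
                                                  agranulocytosis = 0.01),
                       annual_drug_cost = 250,
                       is_clozapine = TRUE)),
    epidemiology = list(
      annual_relapse_prob_no_treatment = 0.45,
      remission_duration = 0.5,
      switch_prob_after_relapse = 0.5,
      adherence_shares = list(full = 0.6, partial = 0.2, none = 0.2),
      adherence_effect_weights = list(full = 1, partial = 0.5, none = 0),
      smr_schizophrenia = 2.5,
      case_fatality = list(agranulocytosis = 0.05, chd = 0.25, stroke = 0.2)),
    utilities = list(
      u_stable = 0.88, u_relapse = 0.6,
      decrements = list(acute_eps = 0.07, sedation = 0.04,
                        sexual_dysfunction = 0.04, weight_gain = 0.04,
                        tardive_dyskinesia = 0.03, agranulocytosis = 0.1,
                        post_chd = 0.12, post_stroke = 0.15, diabetes = 0.07),
      short_term_se_duration = 0.25),
    costs = list(
      annual_stable_care_cost = 10000,
      annual_relapse_episode_cost = 17000,
      per_event_acute_cost = list(chd = 5000, stroke = 12000,
                                  agranulocytosis = 5000, sedation = 150,
                                  weight_gain = 150, acute_eps = 300),
      annual_chronic_cost = list(post_chd = 600, post_stroke = 3000,
                                 diabetes = 1500, tardive_dyskinesia = 400),
      death_cost = 5000, currency_year = 2020),
    risk_models = list(
      diabetes = list(form = "logistic", horizon = 8, intercept = -10.4,
                      variant = "test",
                      terms = list(list(covariate = "glucose", coef = 0.8),
                                   list(covariate = "bmi", coef = 0.07),
                                   list(covariate = "age", coef = 0.03)))),
    life_table = flat_life_table(),
    baseline = list(
      continuous = list(
        age = list(mean = 26, sd = 7, lower = 16, upper = 60),
        bmi = list(mean = 24.5, sd = 4.5, lower = 15, upper = 50),
        total_chol = list(mean = 4.8, sd = 1, lower = 2.5, upper = 10),
        hdl = list(mean = 1.4, sd = 0.35, lower = 0.5, upper = 3.5),
        trig = list(mean = 1.3, sd = 0.8, lower = 0.3, upper = 8),
        glucose = list(mean = 5, sd = 0.7, lower = 3, upper = 15),
        sbp = list(mean = 120, sd = 13, lower = 85, upper = 200)),
      categorical = list(
        sex = list(male = 0.6, female = 0.4),
        smoking = list(current = 0.5, never = 0.5),
        alcohol = list(none = 0.3, moderate = 0.6, high = 0.1),
        adherence = list(full = 0.6, partial = 0.2, none = 0.2)),
      binary = list(prior_chd = 0, prior_stroke = 0, prior_diabetes = 0.02,
                    antihypertensive = 0.02)),
    sim = list(n_patients = 20, n_replications = 2, horizon = 10,
               annual_discount_rate = 0.035,
               wtp_grid = c(0, 20000, 100000), base_wtp = 20000,
               n_psa_draws = 10, psa_n_patients = 10, psa_n_reps = 1,
               master_seed = 42),
    uncertainty = list(
      list(path = "epidemiology/annual_relapse_prob_no_treatment",
           dist = "beta", shape1 = 45, shape2 = 55),
      list(path = "treatments/alpha/relapse_risk_ratio",
           dist = "lognormal", meanlog = log(0.5), sdlog = 0.15),
      list(path = "treatments/alpha/annual_drug_cost",
           dist = "gamma", shape = 25, scale = 4),
      list(path = "utilities/u_relapse",
           dist = "beta", shape1 = 60, shape2 = 40)))
}

test_params <- function(modify = NULL) {
  lst <- test_param_list()
  if (!is.null(modify)) lst <- utils::modifyList(lst, modify)
  parameter_set(lst, quiet = TRUE)
}

# Relapse/remission toy: one effective treatment line with RR 1, no
# discontinuation, no side-effects, no cardio-metabolic risk, no mortality
# within the horizon. Used against Markov/renewal oracles.
markov_toy_params <- function(relapse_prob = 0.45, remission = 0.5) {
  lst <- test_param_list()
  zero_tx <- function(t) {
    t$relapse_risk_ratio <- 1
    t$annual_discontinuation_prob <- 0
    t$annual_td_prob <- 0
    t$metabolic_deltas <- list()
    t$short_term_se_probs <- list()
    t
  }
  lst$treatments <- lapply(lst$treatments, zero_tx)
  lst$treatments$clozapine$is_clozapine <- TRUE
  lst$epidemiology$annual_relapse_prob_no_treatment <- relapse_prob
  lst$epidemiology$remission_duration <- remission
  lst$epidemiology$switch_prob_after_relapse <- 0
  lst$risk_models <- list()
  lst$life_table <- flat_life_table(q = 0)
  lst$baseline$continuous$age <- list(mean = 30, sd = 0, lower = 16, upper = 60)
  lst$baseline$categorical$adherence <- list(full = 1, partial = 0, none = 0)
  parameter_set(lst, quiet = TRUE)
}

# a fixed patient profile for single-trajectory tests
test_profile <- function(...) {
  utils::modifyList(
    list(age = 26, sex = "male", bmi = 24, total_chol = 4.8, hdl = 1.4,
         trig = 1.3, glucose = 5, sbp = 120, smoking = "current",
         antihypertensive = FALSE, prior_chd = FALSE, prior_stroke = FALSE,
         prior_diabetes = FALSE, adherence = "full"),
    list(...))
}

illustrative_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- load_parameter_set(
        system.file("params", "illustrative_uk.yaml", package = "schizosim"),
        quiet = TRUE)
    cache
  }
})
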