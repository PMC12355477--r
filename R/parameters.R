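## Model parameter set: schema, loading, validation, PSA resampling.
##
## The full model configuration travels as a single hierarchical YAML file
## (see inst/params/illustrative_uk.yaml for the documented schema). In R it
## is an "sz_params" list with components: treatments, epidemiology,
## utilities, costs, risk_models, life_table, baseline, sim, uncertainty.

#' Canonical name sets used throughout the model
#'
#' @name canonical-names
#' @keywords internal
NULL

METABOLIC_MARKERS <- c("bmi", "total_chol", "hdl", "trig", "glucose", "sbp")
SHORT_TERM_SES    <- c("acute_eps", "sedation", "sexual_dysfunction",
                       "weight_gain", "agranulocytosis")
CHRONIC_CONDITIONS <- c("post_chd", "post_stroke", "diabetes",
                        "tardive_dyskinesia")
DECREMENT_CONDITIONS <- c("acute_eps", "sedation", "sexual_dysfunction",
                          "weight_gain", "tardive_dyskinesia",
                          "agranulocytosis", "post_chd", "post_stroke",
                          "diabetes")
ADHERENCE_LEVELS <- c("full", "partial", "none")
CM_OUTCOMES <- c("chd", "stroke", "diabetes")
ACUTE_FATAL_EVENTS <- c("agranulocytosis", "chd", "stroke")

## fields that may legitimately be absent from a config file, with defaults
OPTIONAL_DEFAULTS <- list(
  "epidemiology/relapse_counts_without_switch" = TRUE,
  "epidemiology/restart_same_treatment_after_relapse" = TRUE,
  "costs/relapse_cost_dialect" = "per_episode",
  "sim/common_random_numbers" = TRUE,
  "sim/event_guard" = 10000,
  "sim/starting_line" = 1,
  "sim/psa_n_patients" = 200,
  "sim/psa_n_reps" = 20,
  "uncertainty" = list()
)

named_num <- function(x, keys, fill = 0) {
  out <- setNames(rep(fill, length(keys)), keys)
  if (!is.null(x)) {
    x <- unlist(x)
    bad <- setdiff(names(x), keys)
    if (length(bad)) stop_config("unknown key(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- as.numeric(x)
  }
  out
}

#' Load a model parameter set from a YAML configuration file
#'
#' Reads, normalises and validates the full model configuration. Optional
#' fields that are absent are filled with their documented defaults and each
#' defaulted field is reported via `message()` (and recorded in the
#' `"defaulted"` attribute of the result). A life table may be given inline
#' (`life_table:` with `age`, `male`, `female` vectors) or as
#' `life_table_csv:` naming a CSV file (columns `age`, `sex`, `qx`) relative
#' to the configuration file.
#'
#' @param path path to a YAML configuration file.
#' @param quiet suppress the defaulted-field messages.
#' @return a validated `sz_params` object.
#' @seealso [validate_parameter_set()], [write_parameter_set()],
#'   [draw_psa_parameter_set()]
#' @export
load_parameter_set <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  parameter_set(lst, source_dir = dirname(path), quiet = quiet)
}

#' Build a parameter set from a nested list
#'
#' The programmatic equivalent of [load_parameter_set()]; `lst` follows the
#' same schema as the YAML file.
#'
#' @param lst nested list in the configuration schema.
#' @param source_dir directory against which `life_table_csv` is resolved.
#' @param quiet suppress defaulted-field messages.
#' @return a validated `sz_params` object.
#' @export
parameter_set <- function(lst, source_dir = NULL, quiet = FALSE) {
  defaulted <- character(0)
  required <- c("schema_version", "treatments", "epidemiology", "utilities",
                "costs", "risk_models", "baseline", "sim")
  missing <- setdiff(required, names(lst))
  if (length(missing))
    stop_config("missing required field(s): ", paste(missing, collapse = ", "))
  if (is.null(lst[["life_table"]]) && is.null(lst[["life_table_csv"]]))
    stop_config("missing required field(s): life_table (or life_table_csv)")

  get_default <- function(path) {
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    node <- lst
    for (k in parts) node <- node[[k]]
    if (is.null(node)) {
      defaulted <<- c(defaulted, path)
      node <- OPTIONAL_DEFAULTS[[path]]
    }
    node
  }

  ## --- treatments -------------------------------------------------------
  tx_in <- lst$treatments
  if (is.null(names(tx_in)) || any(names(tx_in) == ""))
    stop_config("treatments must be a named map keyed by treatment name")
  treatments <- lapply(names(tx_in), function(nm) {
    t <- tx_in[[nm]]
    need <- c("route", "relapse_risk_ratio", "annual_discontinuation_prob",
              "annual_td_prob", "annual_drug_cost")
    miss <- setdiff(need, names(t))
    if (length(miss))
      stop_config("treatments/", nm, ": missing field(s): ",
                  paste(miss, collapse = ", "))
    list(name = nm,
         route = as.character(t$route),
         relapse_risk_ratio = as.numeric(t$relapse_risk_ratio),
         annual_discontinuation_prob = as.numeric(t$annual_discontinuation_prob),
         annual_td_prob = as.numeric(t$annual_td_prob),
         metabolic_deltas = named_num(t$metabolic_deltas, METABOLIC_MARKERS),
         short_term_se_probs = named_num(t$short_term_se_probs, SHORT_TERM_SES),
         annual_drug_cost = as.numeric(t$annual_drug_cost),
         is_clozapine = isTRUE(t$is_clozapine))
  })
  names(treatments) <- names(tx_in)

  ## --- epidemiology -----------------------------------------------------
  e <- lst$epidemiology
  epidemiology <- list(
    annual_relapse_prob_no_treatment = as.numeric(e$annual_relapse_prob_no_treatment),
    remission_duration = as.numeric(e$remission_duration),
    switch_prob_after_relapse = as.numeric(e$switch_prob_after_relapse),
    adherence_shares = named_num(e$adherence_shares, ADHERENCE_LEVELS),
    adherence_effect_weights = named_num(e$adherence_effect_weights,
                                         ADHERENCE_LEVELS),
    smr_schizophrenia = as.numeric(e$smr_schizophrenia),
    case_fatality = named_num(e$case_fatality, ACUTE_FATAL_EVENTS),
    relapse_counts_without_switch =
      isTRUE(get_default("epidemiology/relapse_counts_without_switch")),
    restart_same_treatment_after_relapse =
      isTRUE(get_default("epidemiology/restart_same_treatment_after_relapse")))

  ## --- utilities --------------------------------------------------------
  u <- lst$utilities
  utilities <- list(
    u_stable = as.numeric(u$u_stable),
    u_relapse = as.numeric(u$u_relapse),
    decrements = named_num(u$decrements, DECREMENT_CONDITIONS),
    short_term_se_duration = as.numeric(u$short_term_se_duration))

  ## --- costs ------------------------------------------------------------
  cc <- lst$costs
  costs <- list(
    annual_stable_care_cost = as.numeric(cc$annual_stable_care_cost),
    annual_relapse_episode_cost = as.numeric(cc$annual_relapse_episode_cost),
    relapse_cost_dialect = as.character(get_default("costs/relapse_cost_dialect")),
    per_event_acute_cost = named_num(cc$per_event_acute_cost,
                                     c(ACUTE_FATAL_EVENTS,
                                       setdiff(SHORT_TERM_SES, "agranulocytosis"))),
    annual_chronic_cost = named_num(cc$annual_chronic_cost, CHRONIC_CONDITIONS),
    death_cost = as.numeric(cc$death_cost),
    currency_year = as.integer(cc$currency_year %||% 2020))

  ## --- risk models ------------------------------------------------------
  risk_models <- lapply(lst$risk_models, function(m) {
    terms <- do.call(rbind, lapply(m$terms, function(tm)
      data.frame(covariate = as.character(tm$covariate),
                 transform = as.character(tm$transform %||% "identity"),
                 coef = as.numeric(tm$coef))))
    list(form = as.character(m$form),
         horizon = as.numeric(m$horizon),
         baseline_survival = if (!is.null(m$baseline_survival))
           as.numeric(m$baseline_survival),
         mean_lp = if (!is.null(m$mean_lp)) as.numeric(m$mean_lp) else 0,
         intercept = if (!is.null(m$intercept)) as.numeric(m$intercept),
         variant = as.character(m$variant %||% "unspecified"),
         terms = terms)
  })

  ## --- life table -------------------------------------------------------
  if (!is.null(lst[["life_table"]])) {
    lt <- lst[["life_table"]]
    life_table <- list(age = as.integer(lt$age),
                       male = as.numeric(lt$male),
                       female = as.numeric(lt$female))
  } else {
    csv <- lst$life_table_csv
    if (!is.null(source_dir) && !file.exists(csv))
      csv <- file.path(source_dir, csv)
    if (!file.exists(csv)) stop_config("life table CSV not found: ", lst$life_table_csv)
    df <- read.csv(csv)
    need <- c("age", "sex", "qx")
    if (!all(need %in% names(df)))
      stop_config("life table CSV must have columns age, sex, qx")
    ages <- sort(unique(df$age))
    life_table <- list(
      age = as.integer(ages),
      male = df$qx[df$sex == "male"][order(df$age[df$sex == "male"])],
      female = df$qx[df$sex == "female"][order(df$age[df$sex == "female"])])
  }
  life_table$max_age <- max(life_table$age)

  ## --- baseline ---------------------------------------------------------
  b <- lst$baseline
  continuous <- lapply(b$continuous, function(v)
    list(mean = as.numeric(v$mean), sd = as.numeric(v$sd),
         lower = as.numeric(v$lower), upper = as.numeric(v$upper)))
  categorical <- lapply(b$categorical, function(v) unlist(v))
  baseline <- list(continuous = continuous,
                   categorical = categorical,
                   binary = named_num(b$binary,
                                      c("prior_chd", "prior_stroke",
                                        "prior_diabetes", "antihypertensive")))

  ## --- simulation settings ---------------------------------------------
  s <- lst$sim
  sim <- list(
    n_patients = as.integer(s$n_patients),
    n_replications = as.integer(s$n_replications),
    horizon = as.numeric(s$horizon),
    annual_discount_rate = as.numeric(s$annual_discount_rate),
    wtp_grid = as.numeric(unlist(s$wtp_grid)),
    base_wtp = as.numeric(s$base_wtp),
    n_psa_draws = as.integer(s$n_psa_draws),
    psa_n_patients = as.integer(get_default("sim/psa_n_patients")),
    psa_n_reps = as.integer(get_default("sim/psa_n_reps")),
    master_seed = as.integer(s$master_seed),
    common_random_numbers = isTRUE(get_default("sim/common_random_numbers")),
    event_guard = as.integer(get_default("sim/event_guard")),
    starting_line = as.integer(get_default("sim/starting_line")))

  ## --- uncertainty map --------------------------------------------------
  unc <- get_default("uncertainty")
  uncertainty <- lapply(unc, function(q) {
    list(path = as.character(q$path),
         dist = as.character(q$dist),
         shape1 = if (!is.null(q$shape1)) as.numeric(q$shape1),
         shape2 = if (!is.null(q$shape2)) as.numeric(q$shape2),
         meanlog = if (!is.null(q$meanlog)) as.numeric(q$meanlog),
         sdlog = if (!is.null(q$sdlog)) as.numeric(q$sdlog),
         shape = if (!is.null(q$shape)) as.numeric(q$shape),
         scale = if (!is.null(q$scale)) as.numeric(q$scale),
         mean = if (!is.null(q$mean)) as.numeric(q$mean),
         sd = if (!is.null(q$sd)) as.numeric(q$sd),
         lower = if (!is.null(q$lower)) as.numeric(q$lower),
         upper = if (!is.null(q$upper)) as.numeric(q$upper))
  })

  p <- structure(list(schema_version = as.integer(lst$schema_version),
                      treatments = treatments,
                      epidemiology = epidemiology,
                      utilities = utilities,
                      costs = costs,
                      risk_models = risk_models,
                      life_table = life_table,
                      baseline = baseline,
                      sim = sim,
                      uncertainty = uncertainty),
                 class = "sz_params")
  attr(p, "defaulted") <- defaulted
  if (!quiet && length(defaulted))
    message("defaulted fields: ", paste(defaulted, collapse = ", "))
  rep <- validate_parameter_set(p)
  if (nrow(rep))
    stop_config("invalid parameter set:\n",
                paste0("  - ", rep$path, ": ", rep$message, collapse = "\n"))
  p
}

#' @export
print.sz_params <- function(x, ...) {
  cat("<sz_params> schema v", x$schema_version, "\n", sep = "")
  cat("  treatments: ", paste(names(x$treatments), collapse = ", "), "\n", sep = "")
  cat("  cohort: ", x$sim$n_patients, " patients x ", x$sim$n_replications,
      " replications, horizon ", x$sim$horizon, " y, discount ",
      100 * x$sim$annual_discount_rate, "%\n", sep = "")
  cat("  uncertain parameters: ", length(x$uncertainty), "\n", sep = "")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every typed invariant of the configuration (probability domains,
#' adherence shares summing to one, utility ordering, non-negative costs,
#' exactly one clozapine profile, agranulocytosis risk restricted to
#' clozapine, life-table domain, resolvable uncertainty paths, ...).
#' Violations are reported, not thrown.
#'
#' @param p an `sz_params` object (or a list in the same shape).
#' @return a data frame with columns `path` and `message`; zero rows iff the
#'   parameter set is valid.
#' @export
validate_parameter_set <- function(p) {
  v <- list()
  add <- function(path, msg) v[[length(v) + 1L]] <<- data.frame(path = path, message = msg)
  chk_prob <- function(x, path) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
      add(path, "probability outside [0, 1]")
  }

  ## treatments
  n_cloz <- sum(vapply(p$treatments, function(t) isTRUE(t$is_clozapine), TRUE))
  if (n_cloz != 1L)
    add("treatments", sprintf("exactly one clozapine profile required (found %d)", n_cloz))
  for (nm in names(p$treatments)) {
    t <- p$treatments[[nm]]
    pre <- paste0("treatments/", nm, "/")
    if (!t$route %in% c("oral", "LAI")) add(paste0(pre, "route"), "must be 'oral' or 'LAI'")
    if (!is_number(t$relapse_risk_ratio) || t$relapse_risk_ratio <= 0)
      add(paste0(pre, "relapse_risk_ratio"), "must be > 0")
    chk_prob(t$annual_discontinuation_prob, paste0(pre, "annual_discontinuation_prob"))
    chk_prob(t$annual_td_prob, paste0(pre, "annual_td_prob"))
    chk_prob(t$short_term_se_probs, paste0(pre, "short_term_se_probs"))
    if (!t$is_clozapine && t$short_term_se_probs[["agranulocytosis"]] > 0)
      add(paste0(pre, "short_term_se_probs/agranulocytosis"),
          "agranulocytosis risk is modelled for clozapine only")
    if (!is_number(t$annual_drug_cost) || t$annual_drug_cost < 0)
      add(paste0(pre, "annual_drug_cost"), "must be >= 0")
    if (any(!is.finite(t$metabolic_deltas)))
      add(paste0(pre, "metabolic_deltas"), "non-finite value")
  }

  ## epidemiology
  e <- p$epidemiology
  chk_prob(e$annual_relapse_prob_no_treatment, "epidemiology/annual_relapse_prob_no_treatment")
  if (!is_number(e$remission_duration) || e$remission_duration < 0)
    add("epidemiology/remission_duration", "must be >= 0")
  chk_prob(e$switch_prob_after_relapse, "epidemiology/switch_prob_after_relapse")
  if (abs(sum(e$adherence_shares) - 1) > 1e-6)
    add("epidemiology/adherence_shares", "shares must sum to 1")
  chk_prob(e$adherence_shares, "epidemiology/adherence_shares")
  w <- e$adherence_effect_weights
  if (any(w < 0 | w > 1)) add("epidemiology/adherence_effect_weights",
                              "weights must lie in [0, 1]")
  if (w[["full"]] != 1) add("epidemiology/adherence_effect_weights/full",
                            "full adherence must map to weight 1")
  if (!is_number(e$smr_schizophrenia) || e$smr_schizophrenia <= 0)
    add("epidemiology/smr_schizophrenia", "must be > 0")
  chk_prob(e$case_fatality, "epidemiology/case_fatality")

  ## utilities
  u <- p$utilities
  if (!is_number(u$u_stable) || u$u_stable < 0 || u$u_stable > 1)
    add("utilities/u_stable", "must lie in [0, 1]")
  if (!is_number(u$u_relapse) || u$u_relapse < 0 || u$u_relapse > u$u_stable)
    add("utilities/u_relapse", "must satisfy 0 <= u_relapse <= u_stable")
  if (any(u$decrements < 0)) add("utilities/decrements", "must be >= 0")
  if (!is_number(u$short_term_se_duration) || u$short_term_se_duration <= 0)
    add("utilities/short_term_se_duration", "must be > 0")

  ## costs
  cc <- p$costs
  for (f in c("annual_stable_care_cost", "annual_relapse_episode_cost", "death_cost"))
    if (!is_number(cc[[f]]) || cc[[f]] < 0) add(paste0("costs/", f), "must be >= 0")
  if (any(cc$per_event_acute_cost < 0)) add("costs/per_event_acute_cost", "must be >= 0")
  if (any(cc$annual_chronic_cost < 0)) add("costs/annual_chronic_cost", "must be >= 0")
  if (!cc$relapse_cost_dialect %in% c("per_episode", "per_year"))
    add("costs/relapse_cost_dialect", "must be 'per_episode' or 'per_year'")

  ## risk models
  known_cov <- c("age", "male", METABOLIC_MARKERS, "smoking",
                 "antihypertensive", "diabetes", "prior_chd", "prior_stroke")
  for (nm in names(p$risk_models)) {
    m <- p$risk_models[[nm]]
    pre <- paste0("risk_models/", nm, "/")
    if (!nm %in% CM_OUTCOMES) add(paste0("risk_models/", nm), "unknown outcome")
    if (!m$form %in% c("cox", "logistic")) add(paste0(pre, "form"), "must be 'cox' or 'logistic'")
    if (!is_number(m$horizon) || m$horizon <= 0) add(paste0(pre, "horizon"), "must be > 0")
    if (identical(m$form, "cox") &&
        (!is_number(m$baseline_survival %||% NA_real_) ||
         m$baseline_survival <= 0 || m$baseline_survival >= 1))
      add(paste0(pre, "baseline_survival"), "must lie in (0, 1)")
    if (identical(m$form, "logistic") && !is_number(m$intercept %||% NA_real_))
      add(paste0(pre, "intercept"), "required for logistic form")
    bad <- setdiff(m$terms$covariate, known_cov)
    if (length(bad)) add(paste0(pre, "terms"),
                         paste0("unknown covariate(s): ", paste(bad, collapse = ", ")))
    if (any(!m$terms$transform %in% c("identity", "log")))
      add(paste0(pre, "terms"), "transform must be 'identity' or 'log'")
  }

  ## life table
  lt <- p$life_table
  if (any(lt$male < 0 | lt$male > 1) || any(lt$female < 0 | lt$female > 1))
    add("life_table", "qx outside [0, 1]")
  if (length(lt$age) != length(lt$male) || length(lt$age) != length(lt$female))
    add("life_table", "age/male/female lengths differ")
  if (length(lt$age) > 1 && any(diff(lt$age) != 1L))
    add("life_table", "ages must be contiguous")
  if (tail(lt$male, 1) != 1 || tail(lt$female, 1) != 1)
    add("life_table", "qx at max_age must be 1")

  ## baseline
  need_cont <- c("age", METABOLIC_MARKERS)
  miss <- setdiff(need_cont, names(p$baseline$continuous))
  if (length(miss)) add("baseline/continuous",
                        paste0("missing: ", paste(miss, collapse = ", ")))
  for (nm in names(p$baseline$continuous)) {
    ch <- p$baseline$continuous[[nm]]
    pre <- paste0("baseline/continuous/", nm)
    if (!is_number(ch$sd) || ch$sd < 0) add(pre, "sd must be >= 0")
    if (!is_number(ch$lower) || !is_number(ch$upper) || ch$lower >= ch$upper)
      add(pre, "bounds must satisfy lower < upper")
  }
  for (nm in names(p$baseline$categorical)) {
    pr <- p$baseline$categorical[[nm]]
    if (abs(sum(pr) - 1) > 1e-6)
      add(paste0("baseline/categorical/", nm), "category probabilities must sum to 1")
    chk_prob(pr, paste0("baseline/categorical/", nm))
  }
  chk_prob(p$baseline$binary, "baseline/binary")
  if (!"adherence" %in% names(p$baseline$categorical))
    add("baseline/categorical", "missing adherence")
  else if (!setequal(names(p$baseline$categorical$adherence), ADHERENCE_LEVELS))
    add("baseline/categorical/adherence",
        "levels must be full/partial/none")

  ## sim
  s <- p$sim
  for (f in c("n_patients", "n_replications", "n_psa_draws",
              "psa_n_patients", "psa_n_reps"))
    if (is.na(s[[f]]) || s[[f]] < 1L) add(paste0("sim/", f), "must be >= 1")
  if (!is_number(s$horizon) || s$horizon <= 0) add("sim/horizon", "must be > 0")
  if (!is_number(s$annual_discount_rate) || s$annual_discount_rate < 0 ||
      s$annual_discount_rate >= 1)
    add("sim/annual_discount_rate", "must lie in [0, 1)")
  if (any(s$wtp_grid < 0)) add("sim/wtp_grid", "must be >= 0")
  if (!s$starting_line %in% c(1L, 2L)) add("sim/starting_line", "must be 1 or 2")

  ## uncertainty paths resolve and distributions are known
  for (i in seq_along(p$uncertainty)) {
    q <- p$uncertainty[[i]]
    pre <- paste0("uncertainty[", i, "]")
    if (!q$dist %in% c("beta", "gamma", "lognormal", "normal", "fixed"))
      add(pre, paste0("unknown distribution: ", q$dist))
    got <- tryCatch(param_get(p, q$path), error = function(e) NULL)
    if (is.null(got)) add(pre, paste0("path does not resolve: ", q$path))
  }

  if (!length(v)) return(data.frame(path = character(0), message = character(0)))
  do.call(rbind, v)
}

#' Resolve / replace a value by its slash-separated parameter path
#'
#' Paths address leaves of the parameter set, e.g.
#' `"treatments/amisulpride/relapse_risk_ratio"`,
#' `"utilities/decrements/weight_gain"`,
#' `"epidemiology/annual_relapse_prob_no_treatment"`.
#'
#' @param p an `sz_params` object.
#' @param path slash-separated path.
#' @param value replacement value (for `param_set`).
#' @return the value at `path` (`param_get`) or the modified parameter set
#'   (`param_set`).
#' @export
param_get <- function(p, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- p
  for (k in parts) {
    if (is.list(node)) {
      if (!k %in% names(node)) stop_config("path does not resolve: ", path)
      node <- node[[k]]
    } else {
      if (!k %in% names(node)) stop_config("path does not resolve: ", path)
      node <- node[[k]]
    }
  }
  node
}

#' @rdname param_get
#' @export
param_set <- function(p, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  rec <- function(node, keys) {
    k <- keys[[1]]
    if (!k %in% names(node)) stop_config("path does not resolve: ", path)
    if (length(keys) == 1L) node[[k]] <- value
    else node[[k]] <- rec(node[[k]], keys[-1])
    node
  }
  out <- rec(unclass(p), parts)
  class(out) <- class(p)
  attributes(out) <- attributes(p)
  out
}

#' Serialise a parameter set back to YAML
#'
#' Writes the documented schema; the life table is written inline so that
#' the file round-trips without external references.
#' `load_parameter_set(write_parameter_set(p, f))` reproduces `p` exactly.
#'
#' @param p an `sz_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(p, path) {
  delist <- function(x) if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  lst <- list(
    schema_version = p$schema_version,
    treatments = lapply(p$treatments, function(t)
      list(route = t$route,
           relapse_risk_ratio = t$relapse_risk_ratio,
           annual_discontinuation_prob = t$annual_discontinuation_prob,
           annual_td_prob = t$annual_td_prob,
           metabolic_deltas = as.list(t$metabolic_deltas),
           short_term_se_probs = as.list(t$short_term_se_probs),
           annual_drug_cost = t$annual_drug_cost,
           is_clozapine = t$is_clozapine)),
    epidemiology = lapply(p$epidemiology, delist),
    utilities = lapply(p$utilities, delist),
    costs = lapply(p$costs, delist),
    risk_models = lapply(p$risk_models, function(m) {
      out <- list(form = m$form, horizon = m$horizon, variant = m$variant,
                  mean_lp = m$mean_lp,
                  terms = lapply(seq_len(nrow(m$terms)), function(i)
                    list(covariate = m$terms$covariate[i],
                         transform = m$terms$transform[i],
                         coef = m$terms$coef[i])))
      if (!is.null(m$baseline_survival)) out$baseline_survival <- m$baseline_survival
      if (!is.null(m$intercept)) out$intercept <- m$intercept
      out
    }),
    life_table = list(age = p$life_table$age,
                      male = p$life_table$male,
                      female = p$life_table$female),
    baseline = list(continuous = p$baseline$continuous,
                    categorical = lapply(p$baseline$categorical, as.list),
                    binary = as.list(p$baseline$binary)),
    sim = p$sim,
    uncertainty = lapply(p$uncertainty, function(q) Filter(Negate(is.null), q)))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

## ---- PSA resampling -----------------------------------------------------

uq_draw <- function(q) {
  switch(q$dist,
         fixed = NULL,
         beta = rbeta(1, q$shape1, q$shape2),
         gamma = rgamma(1, shape = q$shape, scale = q$scale),
         lognormal = rlnorm(1, q$meanlog, q$sdlog),
         normal = rnorm(1, q$mean, q$sd),
         stop_config("unknown distribution: ", q$dist))
}

uq_quantile <- function(q, probs) {
  switch(q$dist,
         beta = qbeta(probs, q$shape1, q$shape2),
         gamma = qgamma(probs, shape = q$shape, scale = q$scale),
         lognormal = qlnorm(probs, q$meanlog, q$sdlog),
         normal = qnorm(probs, q$mean, q$sd),
         fixed = NULL)
}

uq_support <- function(q) {
  lo <- q$lower %||% switch(q$dist, beta = 0, gamma = 0, lognormal = 0, -Inf)
  hi <- q$upper %||% switch(q$dist, beta = 1, Inf)
  c(lo, hi)
}

#' Draw a probabilistic-sensitivity-analysis parameter set
#'
#' Independently redraws every uncertain quantity from its stated
#' distribution (beta for probabilities and utilities, gamma for costs,
#' lognormal for ratios, normal otherwise; `fixed` quantities are left
#' unchanged). Out-of-support draws are rejected and retried; the result is
#' revalidated before being returned.
#'
#' @param p an `sz_params` object with a non-empty uncertainty map (all-fixed
#'   maps are allowed and return `p` unchanged).
#' @param seed optional integer seed for the draw stream; when `NULL` the
#'   current RNG state is used.
#' @param max_retries rejection-sampling bound per quantity.
#' @return a new validated `sz_params` object.
#' @export
draw_psa_parameter_set <- function(p, seed = NULL, max_retries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  out <- p
  for (q in p$uncertainty) {
    if (identical(q$dist, "fixed")) next
    sup <- uq_support(q)
    val <- NULL
    for (i in seq_len(max_retries)) {
      cand <- uq_draw(q)
      if (cand >= sup[1] && cand <= sup[2]) { val <- cand; break }
    }
    if (is.null(val))
      stop_config("could not draw ", q$path, " within its domain after ",
                  max_retries, " attempts")
    out <- param_set(out, q$path, val)
  }
  rep <- validate_parameter_set(out)
  if (nrow(rep))
    stop_config("PSA draw produced an invalid parameter set:\n",
                paste0("  - ", rep$path, ": ", rep$message, collapse = "\n"))
  out
}
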