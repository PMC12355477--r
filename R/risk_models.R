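## Cardio-metabolic risk equations and mortality.
##
## First CHD, first stroke and diabetes onset are driven by published-style
## multivariable risk equations giving a probability over a fixed score
## horizon (e.g. 10 years for CHD/stroke, 8 for diabetes). Coefficients are
## configuration data, not code: each equation is a linear predictor over
## named covariates (optionally log-transformed) combined either as a
## Cox-type score, risk = 1 - S0 ^ exp(lp - mean_lp), or a logistic score,
## risk = plogis(intercept + lp). The horizon risk is converted to an event
## time by a constant-hazard assumption: rate = -log(1 - risk) / horizon.

## fixed covariate layout used by the engine's compiled fast path
COV_LAYOUT <- c("age", "male", METABOLIC_MARKERS, "smoking",
                "antihypertensive", "diabetes", "prior_chd", "prior_stroke")

## Build the named covariate vector from a patient profile (cohort row or
## list). `sex`/`smoking` may be given as categories or already as 0/1.
profile_covariates <- function(profile) {
  pr <- as.list(profile)
  cov <- setNames(numeric(length(COV_LAYOUT)), COV_LAYOUT)
  get <- function(nm) {
    v <- pr[[nm]]
    if (is.null(v) || (length(v) == 1 && is.na(v)))
      stop("missing covariate: ", nm, call. = FALSE)
    v
  }
  cov["age"] <- as.numeric(get("age"))
  cov["male"] <- if (!is.null(pr$male)) as.numeric(pr$male) else
    as.numeric(identical(as.character(get("sex")), "male"))
  for (m in METABOLIC_MARKERS) cov[m] <- as.numeric(get(m))
  cov["smoking"] <- if (is.character(pr$smoking))
    as.numeric(pr$smoking == "current") else as.numeric(get("smoking"))
  cov["antihypertensive"] <- as.numeric(isTRUE(as.logical(pr$antihypertensive)) ||
                                          identical(as.numeric(pr$antihypertensive %||% 0), 1))
  cov["diabetes"] <- as.numeric(isTRUE(as.logical(pr$diabetes %||% pr$prior_diabetes %||% FALSE)))
  cov["prior_chd"] <- as.numeric(isTRUE(as.logical(pr$prior_chd %||% FALSE)))
  cov["prior_stroke"] <- as.numeric(isTRUE(as.logical(pr$prior_stroke %||% FALSE)))
  cov
}

## Compile one risk model against COV_LAYOUT for fast repeated evaluation.
compile_risk_model <- function(m) {
  idx <- match(m$terms$covariate, COV_LAYOUT)
  if (anyNA(idx))
    stop_config("unknown covariate(s): ",
                paste(m$terms$covariate[is.na(idx)], collapse = ", "))
  list(form = m$form, idx = idx, log = m$terms$transform == "log",
       coef = m$terms$coef, horizon = m$horizon,
       log_s0 = if (identical(m$form, "cox")) log(m$baseline_survival),
       mean_lp = m$mean_lp %||% 0, intercept = m$intercept)
}

risk_from_cov <- function(cm, cov) {
  x <- cov[cm$idx]
  if (any(cm$log)) {
    if (any(x[cm$log] <= 0))
      stop("log-transformed covariate must be positive", call. = FALSE)
    x[cm$log] <- log(x[cm$log])
  }
  lp <- sum(cm$coef * x)
  if (identical(cm$form, "cox")) 1 - exp(exp(lp - cm$mean_lp) * cm$log_s0)
  else plogis(cm$intercept + lp)
}

#' Evaluate a risk score for a patient profile
#'
#' Returns the probability of the outcome over the equation's score horizon
#' (in `risk_models[[outcome]]$horizon` years), strictly increasing in each
#' adverse covariate.
#'
#' @param outcome one of `"chd"`, `"stroke"`, `"diabetes"`.
#' @param profile a patient profile: a cohort row, or a list/named vector
#'   with the covariates the equation needs (missing covariates raise an
#'   error naming them).
#' @param risk_models the `risk_models` component of an `sz_params` object.
#' @return a probability in (0, 1).
#' @export
score_risk <- function(outcome, profile, risk_models) {
  m <- risk_models[[outcome]]
  if (is.null(m)) stop_config("no risk model configured for outcome: ", outcome)
  cm <- compile_risk_model(m)
  cov <- profile_covariates(profile)
  risk_from_cov(cm, cov)
}

#' Convert a horizon risk to a sampled event time
#'
#' Constant-hazard conversion: `rate = -log(1 - risk) / horizon`; the event
#' time is exponential with that rate. `risk = 0` returns `Inf` (event never
#' scheduled); `risk = 1` is degenerate and raises an error.
#'
#' @param risk probability over the score horizon, in `[0, 1)`.
#' @param horizon score horizon in years.
#' @param u optional uniform in (0, 1) for deterministic inverse-transform
#'   sampling; when `NULL`, one exponential variate is drawn from the
#'   current RNG stream.
#' @return event time in years (possibly `Inf`).
#' @export
risk_to_time <- function(risk, horizon, u = NULL) {
  stopifnot(horizon > 0, risk >= 0)
  if (risk >= 1) stop("risk = 1 gives a degenerate (zero) event time", call. = FALSE)
  if (risk == 0) return(Inf)
  rate <- -log1p(-risk) / horizon
  if (is.null(u)) rexp(1, rate) else qexp(u, rate)
}

## Precompute per-sex cumulative-hazard step functions from the life table,
## with the schizophrenia standardised mortality ratio applied as
## q' = 1 - (1 - q)^SMR, i.e. annual hazard scaled by SMR.
compile_mortality <- function(life_table, smr) {
  haz <- function(q) ifelse(q >= 1, Inf, -smr * log1p(-q))
  list(age0 = life_table$age[1], max_age = life_table$max_age,
       h = list(male = haz(life_table$male), female = haz(life_table$female)))
}

sample_death_time_compiled <- function(mort, age, sex, u) {
  a0 <- floor(age)
  i0 <- a0 - mort$age0 + 1L
  h <- mort$h[[sex]]
  if (i0 < 1L || a0 > mort$max_age) stop("age outside life-table support", call. = FALSE)
  ## interval widths: partial first year (to the next integer age), then 1 y
  widths <- c(1 - (age - a0), rep(1, length(h) - i0))
  hh <- h[i0:length(h)]
  target <- -log(u)
  cum <- 0
  for (k in seq_along(hh)) {
    inc <- hh[k] * widths[k]
    if (!is.finite(inc) || cum + inc >= target) {
      within <- if (!is.finite(hh[k])) 0 else (target - cum) / hh[k]
      return(sum(widths[seq_len(k - 1L)]) + min(within, widths[k]))
    }
    cum <- cum + inc
  }
  ## q(max_age) = 1 makes the last hazard infinite, so this is unreachable;
  ## cap defensively at the table end.
  sum(widths)
}

#' Sample a time to death from a life table
#'
#' Inverse-transform sample from the survival curve obtained by compounding
#' annual death probabilities adjusted for the schizophrenia standardised
#' mortality ratio, `q' = 1 - (1 - q)^smr`, with a constant hazard within
#' each year of age. Death is certain by `max_age` (where `q = 1` by
#' convention).
#'
#' @param age current age in years (may be fractional).
#' @param sex `"male"` or `"female"`.
#' @param life_table the `life_table` component of an `sz_params` object.
#' @param smr standardised mortality ratio (> 0).
#' @param u optional uniform in (0, 1); when `NULL` one is drawn.
#' @return time to death in years from now.
#' @export
sample_time_to_death <- function(age, sex, life_table, smr, u = NULL) {
  stopifnot(smr > 0)
  mort <- compile_mortality(life_table, smr)
  sample_death_time_compiled(mort, age, sex, u %||% runif(1))
}

#' Draw survival of an acute event
#'
#' Bernoulli case-fatality at the occurrence of agranulocytosis, CHD or
#' stroke.
#'
#' @param event one of `"agranulocytosis"`, `"chd"`, `"stroke"`.
#' @param epi the `epidemiology` component of an `sz_params` object.
#' @param u optional uniform in (0, 1).
#' @return `TRUE` if the patient dies at the event.
#' @export
acute_fatality <- function(event, epi, u = NULL) {
  if (!event %in% names(epi$case_fatality))
    stop_config("no case fatality configured for event: ", event)
  (u %||% runif(1)) < epi$case_fatality[[event]]
}
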