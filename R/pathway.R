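## Treatment-line logic and schizophrenia-specific event-time samplers.
##
## All waiting times are exponential (annual probabilities converted to
## constant hazards): relapse under a treatment-specific risk ratio modified
## by adherence, all-cause discontinuation and tardive dyskinesia under
## treatment-specific annual probabilities. Remission is deterministic at a
## fixed episode duration. Patients switch line with a fixed probability at
## relapse; the third and last line is always clozapine, reached at the
## first switch after two consecutive failures (relapses).

#' Relapse hazard rate for a patient state
#'
#' Base rate is `-log(1 - p)` with `p` the annual relapse probability under
#' no treatment. On treatment the hazard is multiplied by
#' `1 + (RR - 1) * w`, where `RR` is the treatment's relapse risk ratio and
#' `w` the adherence effect weight (1 = full adherence gives the full
#' treatment effect, 0 = non-adherence gives the untreated hazard).
#' Long-acting injectables force full adherence.
#'
#' @param epi the `epidemiology` component of an `sz_params` object.
#' @param treatment a treatment profile (element of `p$treatments`) or
#'   `NULL` when off treatment.
#' @param adherence adherence level (`"full"`, `"partial"`, `"none"`).
#' @return hazard rate per year.
#' @export
relapse_rate <- function(epi, treatment = NULL, adherence = "full") {
  base <- prob_to_rate(epi$annual_relapse_prob_no_treatment)
  if (is.null(treatment)) return(base)
  w <- if (identical(treatment$route, "LAI")) 1
       else epi$adherence_effect_weights[[adherence]]
  base * (1 + (treatment$relapse_risk_ratio - 1) * w)
}

#' Sample a time to relapse
#'
#' @param state list with `disease_state`, `on_treatment`, `treatment`
#'   (profile or `NULL`) and `adherence`.
#' @param epi the `epidemiology` component of an `sz_params` object.
#' @param u optional uniform in (0, 1) for inverse-transform sampling.
#' @return waiting time in years.
#' @export
sample_time_to_relapse <- function(state, epi, u = NULL) {
  if (identical(state$disease_state, "relapse"))
    stop("relapse cannot be scheduled during an ongoing relapse episode",
         call. = FALSE)
  tx <- if (isTRUE(state$on_treatment)) state$treatment else NULL
  rate <- relapse_rate(epi, tx, state$adherence %||% "full")
  if (rate <= 0) return(Inf)
  if (is.null(u)) rexp(1, rate) else qexp(u, rate)
}

#' Schedule the (deterministic) remission ending a relapse episode
#'
#' @param relapse_time absolute time of the relapse (years), or a state list
#'   with a `time` field.
#' @param epi the `epidemiology` component of an `sz_params` object.
#' @return absolute remission time.
#' @export
schedule_remission <- function(relapse_time, epi) {
  t <- if (is.list(relapse_time)) relapse_time$time else relapse_time
  t + epi$remission_duration
}

#' Sample a time to all-cause treatment discontinuation
#'
#' @param treatment a treatment profile.
#' @param u optional uniform in (0, 1).
#' @return waiting time in years (`Inf` when the annual probability is 0).
#' @export
sample_time_to_discontinuation <- function(treatment, u = NULL) {
  rate <- prob_to_rate(treatment$annual_discontinuation_prob)
  if (rate <= 0) return(Inf)
  if (is.null(u)) rexp(1, rate) else qexp(u, rate)
}

#' Sample a time to tardive dyskinesia while on a treatment
#'
#' The clock runs only while on treatment and the condition occurs at most
#' once per patient (the engine suspends/redraws it across treatment
#' episodes, which is distribution-preserving for exponential clocks).
#'
#' @inheritParams sample_time_to_discontinuation
#' @return waiting time in years.
#' @export
sample_time_to_td <- function(treatment, u = NULL) {
  rate <- prob_to_rate(treatment$annual_td_prob)
  if (rate <= 0) return(Inf)
  if (is.null(u)) rexp(1, rate) else qexp(u, rate)
}

## Where does a switch at relapse lead? NULL = no further line (clozapine is
## absorbing). `failures` counts consecutive failures *including* the
## current relapse.
switch_target <- function(line_index, failures, sequence) {
  if (line_index >= 3L) return(NULL)
  if (failures >= 2L) sequence[[3L]] else sequence[[line_index + 1L]]
}

#' Start (or restart) a treatment for a patient state
#'
#' Applies the treatment's metabolic shifts to the profile, draws the
#' short-term side-effects (Bernoulli within the first three months of
#' treatment), including agranulocytosis with its case-fatality check for
#' clozapine, and marks the treatment as tried. Clock rescheduling is the
#' engine's job; this function returns the state change and the draws.
#'
#' @param state list with fields `time`, `profile` (named covariates or a
#'   cohort row), `on_treatment`, `tried` (character vector).
#' @param treatment a treatment profile.
#' @param p an `sz_params` object.
#' @return list with `state` (updated), `se_occurred` (named logical over
#'   short-term side-effects) and `agran_fatal` (logical).
#' @export
apply_treatment_start <- function(state, treatment, p) {
  if (isTRUE(state$on_treatment))
    stop("cannot start a treatment while another is active", call. = FALSE)
  if (treatment$name %in% (state$tried %||% character(0)) &&
      !identical(state$current_treatment, treatment$name))
    stop("treatment already tried: ", treatment$name, call. = FALSE)
  cov <- profile_covariates(state$profile)
  cov[METABOLIC_MARKERS] <- cov[METABOLIC_MARKERS] + treatment$metabolic_deltas
  pr <- treatment$short_term_se_probs
  u <- runif(length(pr))
  occurred <- u < pr
  names(occurred) <- names(pr)
  if (!treatment$is_clozapine) occurred[["agranulocytosis"]] <- FALSE
  agran_fatal <- FALSE
  if (occurred[["agranulocytosis"]])
    agran_fatal <- acute_fatality("agranulocytosis", p$epidemiology)
  state$profile <- cov
  state$on_treatment <- TRUE
  state$current_treatment <- treatment$name
  state$tried <- union(state$tried %||% character(0), treatment$name)
  list(state = state, se_occurred = occurred, agran_fatal = agran_fatal)
}

#' Resolve a relapse event: episode bookkeeping and the switch decision
#'
#' Increments the consecutive-failure counter, schedules remission, and with
#' the configured probability decides a switch to the next line (clozapine
#' at the first switch after two consecutive failures; patients already on
#' clozapine never switch).
#'
#' @param state list with `time` (relapse time), `line_index`,
#'   `consecutive_failures`, `on_treatment`, `disease_state`.
#' @param sequence character vector of length 3 (first line, second line,
#'   clozapine).
#' @param epi the `epidemiology` component of an `sz_params` object.
#' @param u optional uniform in (0, 1) for the switch draw.
#' @return list with `state` (updated: `disease_state = "relapse"`,
#'   `remission_time`, counters), `switched` and `next_treatment` (name or
#'   `NULL`).
#' @export
resolve_relapse <- function(state, sequence, epi, u = NULL) {
  state$disease_state <- "relapse"
  state$remission_time <- schedule_remission(state$time, epi)
  can_switch <- state$line_index < 3L
  switched <- can_switch &&
    (u %||% runif(1)) < epi$switch_prob_after_relapse
  counts <- switched || isTRUE(epi$relapse_counts_without_switch)
  if (counts)
    state$consecutive_failures <- (state$consecutive_failures %||% 0L) + 1L
  nxt <- NULL
  if (switched) {
    nxt <- switch_target(state$line_index, state$consecutive_failures, sequence)
    state$line_index <- if (identical(nxt, sequence[[3L]])) 3L
                        else state$line_index + 1L
  }
  list(state = state, switched = switched, next_treatment = nxt)
}
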