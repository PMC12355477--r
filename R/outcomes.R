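## Trajectory -> discounted / undiscounted QALYs and costs.
##
## Utilities: a state utility (stable vs relapse) minus additive decrements
## for active conditions, floored at zero (when the floor binds, losses are
## attributed to conditions pro rata so the decomposition still sums).
## QALY-loss buckets: "cardiometabolic" = post-CHD/post-stroke/diabetes
## decrements; "other side-effects" = acute EPS, weight gain, sedation,
## sexual dysfunction, tardive dyskinesia (and agranulocytosis).
## Discounting is continuous-time at an annual rate r:
## weight(t0, t1) = ((1+r)^-t0 - (1+r)^-t1) / log(1+r).

SUMMARY_COLS <- c(
  "years_stable", "years_relapse", "life_years",
  "qalys_excl_se", "qaly_loss_cardiometabolic", "qaly_loss_other_se",
  "qalys_undiscounted", "qalys_discounted",
  "cost_drug", "cost_stable_care", "cost_relapse", "cost_se_management",
  "cost_cardiometabolic", "cost_death", "total_cost_discounted",
  "n_relapses")

CM_DECREMENTS <- c("post_chd", "post_stroke", "diabetes")
OTHER_DECREMENTS <- c("acute_eps", "sedation", "sexual_dysfunction",
                      "weight_gain", "tardive_dyskinesia", "agranulocytosis")

#' Continuous-time discounted duration
#'
#' The exact integral of the discount factor over an interval:
#' `weight(t0, t1) = ((1+r)^-t0 - (1+r)^-t1) / log(1+r)`; for `r = 0` this
#' is `t1 - t0`. Additive over adjacent intervals.
#'
#' @param r annual discount rate (>= 0).
#' @param t0,t1 interval bounds in years, `0 <= t0 <= t1`.
#' @return discounted duration in years.
#' @export
discount_weight <- function(r, t0, t1) {
  stopifnot(r >= 0, t0 >= 0)
  if (any(t1 < t0)) stop("t1 must be >= t0", call. = FALSE)
  if (r == 0) return(t1 - t0)
  lg <- log1p(r)
  (exp(-t0 * lg) - exp(-t1 * lg)) / lg
}

discount_factor <- function(r, t) if (r == 0) rep(1, length(t)) else exp(-t * log1p(r))

compile_outcomes <- function(p) {
  list(r = p$sim$annual_discount_rate,
       H = p$sim$horizon,
       u_stable = p$utilities$u_stable,
       u_relapse = p$utilities$u_relapse,
       dec = p$utilities$decrements,
       dur_se = p$utilities$short_term_se_duration,
       dialect = p$costs$relapse_cost_dialect,
       stable_rate = p$costs$annual_stable_care_cost,
       relapse_cost = p$costs$annual_relapse_episode_cost,
       acute = p$costs$per_event_acute_cost,
       chronic = p$costs$annual_chronic_cost,
       death_cost = p$costs$death_cost,
       drug_cost = vapply(p$treatments, `[[`, 0, "annual_drug_cost"))
}

## Utility and rate bookkeeping for one constant-state interval.
## perm: named logical over c(post_chd, post_stroke, diabetes,
## tardive_dyskinesia); st_active: character vector of active short-term
## side-effects. Returns increments for SUMMARY_COLS (partial).
interval_increments <- function(o, stable, on_tx, cur_cost, perm, st_active,
                                t0, t1) {
  dur <- t1 - t0
  dw <- discount_weight(o$r, t0, t1)
  base_u <- if (stable) o$u_stable else o$u_relapse
  dec_cm <- sum(o$dec[CM_DECREMENTS][perm[CM_DECREMENTS]])
  dec_other <- sum(o$dec[st_active]) +
    if (perm[["tardive_dyskinesia"]]) o$dec[["tardive_dyskinesia"]] else 0
  tot <- dec_cm + dec_other
  if (tot > base_u && tot > 0) {          # utility floored at zero
    scl <- base_u / tot
    dec_cm <- dec_cm * scl
    dec_other <- dec_other * scl
    tot <- base_u
  }
  eff <- base_u - tot
  inc <- setNames(numeric(length(SUMMARY_COLS)), SUMMARY_COLS)
  if (stable) inc["years_stable"] <- dur else inc["years_relapse"] <- dur
  inc["qalys_excl_se"] <- base_u * dur
  inc["qaly_loss_cardiometabolic"] <- -dec_cm * dur
  inc["qaly_loss_other_se"] <- -dec_other * dur
  inc["qalys_undiscounted"] <- eff * dur
  inc["qalys_discounted"] <- eff * dw
  if (on_tx) inc["cost_drug"] <- cur_cost * dw
  if (identical(o$dialect, "per_year")) {
    if (stable) inc["cost_stable_care"] <- o$stable_rate * dw
    else inc["cost_relapse"] <- o$relapse_cost * dw
  } else {
    inc["cost_stable_care"] <- o$stable_rate * dw
  }
  inc["cost_cardiometabolic"] <- sum(o$chronic[CM_DECREMENTS][perm[CM_DECREMENTS]]) * dw
  if (perm[["tardive_dyskinesia"]])
    inc["cost_se_management"] <- o$chronic[["tardive_dyskinesia"]] * dw
  inc
}

#' Accrue utilities and costs over a constant-state interval
#'
#' The engine guarantees state changes only at event times; this accrues
#' QALY and cost components over `[t0, t1]` for a constant state. Utility is
#' `max(0, state utility - sum of active decrements)`; drug cost accrues
#' while on treatment; chronic condition costs accrue for active long-term
#' conditions; care costs follow the relapse-cost dialect (`per_episode`:
#' background care cost in both states, episode cost lumped at relapse;
#' `per_year`: state-specific care rates, no lump).
#'
#' @param state list with `disease_state` (`"stable"`/`"relapse"`),
#'   `on_treatment`, `treatment` (name, used for the drug cost) and
#'   `active_conditions` (character vector over decrement names).
#' @param t0,t1 interval bounds (years).
#' @param p an `sz_params` object.
#' @return named numeric vector of component increments (QALY buckets
#'   undiscounted, `qalys_discounted` and cost buckets discounted).
#' @export
accrue_interval <- function(state, t0, t1, p) {
  o <- compile_outcomes(p)
  act <- state$active_conditions %||% character(0)
  perm <- setNames(c(CM_DECREMENTS, "tardive_dyskinesia") %in% act,
                   c(CM_DECREMENTS, "tardive_dyskinesia"))
  st <- intersect(act, setdiff(OTHER_DECREMENTS, "tardive_dyskinesia"))
  cur_cost <- if (isTRUE(state$on_treatment))
    o$drug_cost[[state$treatment]] else 0
  interval_increments(o, identical(state$disease_state %||% "stable", "stable"),
                      isTRUE(state$on_treatment), cur_cost, perm, st, t0, t1)
}

#' Apply the instantaneous outcome of an event
#'
#' Lump costs at the event time's discount factor (relapse episode cost
#' under the per-episode dialect, acute CHD/stroke costs, short-term
#' side-effect management costs at treatment start, death cost) and the
#' conditions the event activates for subsequent accrual.
#'
#' @param type event type (see `EVENT_TYPES`, plus `"treatment_start"` and
#'   `"horizon_end"`).
#' @param time event time in years.
#' @param p an `sz_params` object.
#' @param payload optional details: `fatal` for CHD/stroke,
#'   `side_effects` (character) for treatment start.
#' @return list with `costs` (named increments over cost buckets) and
#'   `activate` (character vector of conditions becoming active).
#' @export
apply_event_outcomes <- function(type, time, p, payload = list()) {
  o <- compile_outcomes(p)
  df <- discount_factor(o$r, time)
  costs <- c(cost_relapse = 0, cost_se_management = 0,
             cost_cardiometabolic = 0, cost_death = 0)
  activate <- character(0)
  if (type == "relapse") {
    if (identical(o$dialect, "per_episode"))
      costs["cost_relapse"] <- o$relapse_cost * df
  } else if (type %in% c("chd", "stroke")) {
    costs["cost_cardiometabolic"] <- o$acute[[type]] * df
    if (!isTRUE(payload$fatal))
      activate <- paste0("post_", type)
  } else if (type == "treatment_start") {
    ses <- payload$side_effects %||% character(0)
    costs["cost_se_management"] <- sum(o$acute[ses]) * df
    activate <- ses
  } else if (type == "tardive_dyskinesia") {
    activate <- "tardive_dyskinesia"
  } else if (type == "diabetes") {
    activate <- "diabetes"
  } else if (type == "death") {
    costs["cost_death"] <- o$death_cost * df
  } else if (!type %in% ALL_EVENT_TYPES) {
    stop("unknown event type: ", type, call. = FALSE)
  }
  list(costs = costs, activate = activate)
}

## Replay a raw trajectory into its outcome summary (fast path shared by
## run_cohort and summarise_trajectory).
summarise_raw <- function(raw, o, prior) {
  out <- setNames(numeric(length(SUMMARY_COLS)), SUMMARY_COLS)
  stable <- TRUE
  on_tx <- FALSE
  cur_cost <- 0
  perm <- c(post_chd = isTRUE(prior[["prior_chd"]]),
            post_stroke = isTRUE(prior[["prior_stroke"]]),
            diabetes = isTRUE(prior[["prior_diabetes"]]),
            tardive_dyskinesia = FALSE)
  st_exp <- setNames(rep(-Inf, 5L), names(SE_BITS))
  t_prev <- 0
  n <- length(raw$time)
  for (k in seq_len(n)) {
    tE <- raw$time[k]
    if (tE > t_prev) {
      cuts <- st_exp[st_exp > t_prev & st_exp < tE]
      bounds <- c(t_prev, sort(cuts), tE)
      for (b in seq_len(length(bounds) - 1L)) {
        a0 <- bounds[b]; a1 <- bounds[b + 1L]
        st_act <- names(st_exp)[st_exp > a0]
        out <- out + interval_increments(o, stable, on_tx, cur_cost, perm,
                                         st_act, a0, a1)
      }
      t_prev <- tE
    }
    ty <- raw$type[k]
    df <- discount_factor(o$r, tE)
    if (ty == EV_TXSTART) {
      on_tx <- TRUE
      cur_cost <- o$drug_cost[[raw$tx[k]]]
      fl <- raw$flags[k]
      occ <- bitwAnd(fl, SE_BITS) > 0L
      ses <- names(SE_BITS)[occ]
      if (length(ses)) {
        st_exp[ses] <- pmax(st_exp[ses], tE + o$dur_se)
        out["cost_se_management"] <- out["cost_se_management"] +
          sum(o$acute[ses]) * df
      }
    } else if (ty == EV_RELAPSE) {
      stable <- FALSE
      out["n_relapses"] <- out["n_relapses"] + 1
      if (identical(o$dialect, "per_episode"))
        out["cost_relapse"] <- out["cost_relapse"] + o$relapse_cost * df
    } else if (ty == EV_REMISSION) {
      stable <- TRUE
    } else if (ty == EV_DISCONT) {
      on_tx <- FALSE
    } else if (ty == EV_TD) {
      perm[["tardive_dyskinesia"]] <- TRUE
    } else if (ty == EV_DIABETES) {
      perm[["diabetes"]] <- TRUE
    } else if (ty == EV_CHD || ty == EV_STROKE) {
      nm <- if (ty == EV_CHD) "chd" else "stroke"
      out["cost_cardiometabolic"] <- out["cost_cardiometabolic"] +
        o$acute[[nm]] * df
      if (raw$flags[k] == 0L) perm[[paste0("post_", nm)]] <- TRUE
    } else if (ty == EV_DEATH) {
      out["cost_death"] <- o$death_cost * df
      break
    } else if (ty == EV_HORIZON) {
      break
    }
  }
  out["life_years"] <- t_prev
  out["total_cost_discounted"] <- out["cost_drug"] + out["cost_stable_care"] +
    out["cost_relapse"] + out["cost_se_management"] +
    out["cost_cardiometabolic"] + out["cost_death"]
  out
}

#' Summarise a trajectory into its QALY and cost decomposition
#'
#' Deterministic given the trajectory: replays the event list, accruing
#' utilities and costs between events and applying event lumps, and returns
#' the outcome decomposition (undiscounted years in stable state, QALYs
#' excluding side-effect losses, QALY losses from cardio-metabolic
#' conditions and from other side-effects, discounted QALYs, and discounted
#' cost components with their total).
#'
#' @param traj an `sz_trajectory` from [simulate_patient()].
#' @param p an `sz_params` object.
#' @return a one-row data frame with the summary columns.
#' @export
summarise_trajectory <- function(traj, p) {
  o <- compile_outcomes(p)
  ev <- traj$events
  raw <- list(time = ev$time,
              type = match(ev$type, ALL_EVENT_TYPES),
              tx = match(ev$treatment, names(p$treatments)),
              flags = ev$flags)
  if (anyNA(raw$type)) stop("unknown event type in trajectory", call. = FALSE)
  raw$tx[is.na(raw$tx)] <- 0L
  res <- summarise_raw(raw, o, traj$prior %||%
                         c(prior_chd = FALSE, prior_stroke = FALSE,
                           prior_diabetes = FALSE))
  as.data.frame(as.list(res))
}
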