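## The DES core: event scheduling, selection, state update, trajectory
## recording.
##
## Per patient, a list of absolute times to each candidate event is held;
## the loop picks the earliest, updates state, and regenerates only the
## clocks whose hazard changed (memoryless exponential clocks may keep their
## scheduled times otherwise, which also stabilises common random numbers).
## The loop ends at death or the time horizon.

## event codes; the order IS the tie-break priority (death first prevents
## post-mortem events at exact ties)
EVENT_TYPES <- c("death", "chd", "stroke", "diabetes", "relapse",
                 "remission", "discontinuation", "tardive_dyskinesia")
EV_DEATH <- 1L; EV_CHD <- 2L; EV_STROKE <- 3L; EV_DIABETES <- 4L
EV_RELAPSE <- 5L; EV_REMISSION <- 6L; EV_DISCONT <- 7L; EV_TD <- 8L
EV_TXSTART <- 9L; EV_HORIZON <- 10L
ALL_EVENT_TYPES <- c(EVENT_TYPES, "treatment_start", "horizon_end")

## short-term side-effect bits in the treatment_start flags payload
SE_BITS <- c(acute_eps = 1L, sedation = 2L, sexual_dysfunction = 4L,
             weight_gain = 8L, agranulocytosis = 16L)
FLAG_AGRAN_FATAL <- 32L
## death causes stored in the death event's flags
DEATH_CAUSES <- c("background", "chd", "stroke", "agranulocytosis")

#' Select the next event from a pending map
#'
#' Returns the earliest pending event; exact ties are broken by the fixed
#' priority order death > CHD > stroke > diabetes > relapse > remission >
#' discontinuation > tardive dyskinesia.
#'
#' @param pending named numeric vector of absolute event times (may contain
#'   `Inf` for unscheduled clocks); names must be event types.
#' @return list with `type` and `time`.
#' @export
next_event <- function(pending) {
  pending <- pending[is.finite(pending) | pending == Inf]
  if (!length(pending) || all(!is.finite(pending)))
    stop("no pending events", call. = FALSE)
  bad <- setdiff(names(pending), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ord <- match(EVENT_TYPES, names(pending))
  ord <- ord[!is.na(ord)]
  pending <- pending[ord]  # priority order; which.min takes the first min
  j <- which.min(pending)
  list(type = names(pending)[j], time = unname(pending[j]))
}

## ---- model compilation --------------------------------------------------

compile_model <- function(p) {
  tx <- lapply(p$treatments, function(t) {
    list(name = t$name,
         disc_rate = prob_to_rate(t$annual_discontinuation_prob),
         td_rate = prob_to_rate(t$annual_td_prob),
         rr = t$relapse_risk_ratio,
         lai = identical(t$route, "LAI"),
         deltas = unname(t$metabolic_deltas[METABOLIC_MARKERS]),
         se_probs = unname(t$short_term_se_probs[SHORT_TERM_SES]),
         is_clozapine = t$is_clozapine,
         drug_cost = t$annual_drug_cost)
  })
  cm <- lapply(p$risk_models, compile_risk_model)
  list(tx = tx, tx_names = names(p$treatments), cm = cm,
       cm_names = names(cm),
       mort = compile_mortality(p$life_table, p$epidemiology$smr_schizophrenia),
       base_relapse_rate = prob_to_rate(p$epidemiology$annual_relapse_prob_no_treatment),
       adh_w = p$epidemiology$adherence_effect_weights,
       pi_switch = p$epidemiology$switch_prob_after_relapse,
       d_rem = p$epidemiology$remission_duration,
       cf = p$epidemiology$case_fatality,
       counts_wo_switch = p$epidemiology$relapse_counts_without_switch,
       restart = p$epidemiology$restart_same_treatment_after_relapse,
       horizon = p$sim$horizon,
       guard = p$sim$event_guard,
       starting_line = p$sim$starting_line)
}

## ---- per-patient simulation (internal, raw form) ------------------------

## seq_ids: indices into ctx$tx, length 3 (line1, line2, clozapine).
## Returns list(time, type, tx, flags) plus meta needed for outcome replay.
sim_patient_raw <- function(ctx, cov, sex, adherence, seq_ids,
                            seed_death, seed_traj) {
  H <- ctx$horizon
  MARKER_IDX <- match(METABOLIC_MARKERS, COV_LAYOUT)
  cap <- 64L
  ev_t <- numeric(cap); ev_y <- integer(cap)
  ev_x <- integer(cap); ev_f <- integer(cap)
  ne <- 0L
  rec <- function(time, type, tx = 0L, flags = 0L) {
    ne <<- ne + 1L
    if (ne > cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_y) <<- cap
      length(ev_x) <<- cap; length(ev_f) <<- cap
    }
    ev_t[ne] <<- time; ev_y[ne] <<- type
    ev_x[ne] <<- tx; ev_f[ne] <<- flags
  }

  age0 <- cov[["age"]]
  set.seed(seed_death)
  t_death <- sample_death_time_compiled(ctx$mort, age0, sex, runif(1))
  set.seed(seed_traj)

  pending <- rep(Inf, 8L)
  pending[EV_DEATH] <- t_death
  disease_stable <- TRUE
  on_tx <- FALSE
  cur <- 0L
  line <- ctx$starting_line
  failures <- if (line > 1L) 1L else 0L
  td_done <- FALSE
  restart_pending <- FALSE
  alive <- TRUE
  adh_weight <- ctx$adh_w[[adherence]]

  cm_n <- length(ctx$cm)
  cm_ev <- match(ctx$cm_names, c("", "chd", "stroke", "diabetes"))
  cm_done <- logical(cm_n)
  if (cm_n) {
    cm_done <- vapply(ctx$cm_names, function(o)
      switch(o, chd = cov[["prior_chd"]] == 1,
             stroke = cov[["prior_stroke"]] == 1,
             diabetes = cov[["diabetes"]] == 1), TRUE)
  }
  cm_rate <- rep(NA_real_, cm_n)

  resched_cm <- function(t) {
    if (!cm_n) return(invisible())
    cov["age"] <<- age0 + t
    for (k in seq_len(cm_n)) {
      if (cm_done[k]) next
      risk <- risk_from_cov(ctx$cm[[k]], cov)
      rate <- -log1p(-risk) / ctx$cm[[k]]$horizon
      if (is.na(cm_rate[k]) || rate != cm_rate[k]) {
        cm_rate[k] <<- rate
        pending[cm_ev[k]] <<- if (rate > 0) t + rexp(1, rate) else Inf
      }
    }
  }

  sched_relapse <- function(t) {
    if (!disease_stable || !alive) { pending[EV_RELAPSE] <<- Inf; return(invisible()) }
    rate <- ctx$base_relapse_rate
    if (on_tx) {
      tx <- ctx$tx[[cur]]
      w <- if (tx$lai) 1 else adh_weight
      rate <- rate * (1 + (tx$rr - 1) * w)
    }
    pending[EV_RELAPSE] <<- if (rate > 0) t + rexp(1, rate) else Inf
  }

  stop_tx <- function() {
    tx <- ctx$tx[[cur]]
    cov[MARKER_IDX] <<- cov[MARKER_IDX] - tx$deltas
    on_tx <<- FALSE
    pending[EV_DISCONT] <<- Inf
    pending[EV_TD] <<- Inf
  }

  start_tx <- function(id, t) {
    tx <- ctx$tx[[id]]
    on_tx <<- TRUE
    cur <<- id
    cov[MARKER_IDX] <<- cov[MARKER_IDX] + tx$deltas
    u <- runif(5L)  # fixed draw count keeps streams aligned across sequences
    occ <- u < tx$se_probs
    if (!tx$is_clozapine) occ[5L] <- FALSE
    flags <- sum(SE_BITS[occ])
    fatal <- FALSE
    if (occ[5L] && runif(1) < ctx$cf[["agranulocytosis"]]) {
      fatal <- TRUE
      flags <- flags + FLAG_AGRAN_FATAL
    }
    rec(t, EV_TXSTART, id, as.integer(flags))
    if (fatal) {
      rec(t, EV_DEATH, 0L, 4L)  # cause index into DEATH_CAUSES
      alive <<- FALSE
      return(invisible())
    }
    pending[EV_DISCONT] <<- if (tx$disc_rate > 0) t + rexp(1, tx$disc_rate) else Inf
    pending[EV_TD] <<- if (!td_done && tx$td_rate > 0) t + rexp(1, tx$td_rate) else Inf
    sched_relapse(t)
    resched_cm(t)
  }

  start_tx(seq_ids[if (line >= 3L) 3L else 1L], 0)

  it <- 0L
  while (alive) {
    it <- it + 1L
    if (it > ctx$guard)
      stop("event-count guard exceeded (", ctx$guard,
           " events in one trajectory); check hazard parameters", call. = FALSE)
    j <- which.min(pending)
    tE <- pending[j]
    if (tE >= H) { rec(H, EV_HORIZON); break }
    if (j == EV_DEATH) {
      rec(tE, EV_DEATH, 0L, 1L)
      break
    } else if (j == EV_CHD || j == EV_STROKE) {
      nm <- if (j == EV_CHD) "chd" else "stroke"
      fatal <- runif(1) < ctx$cf[[nm]]
      rec(tE, j, 0L, as.integer(fatal))
      if (fatal) {
        rec(tE, EV_DEATH, 0L, if (j == EV_CHD) 2L else 3L)
        break
      }
      k <- match(nm, ctx$cm_names)
      cm_done[k] <- TRUE
      pending[j] <- Inf
      cov[[if (j == EV_CHD) "prior_chd" else "prior_stroke"]] <- 1
      resched_cm(tE)
    } else if (j == EV_DIABETES) {
      rec(tE, EV_DIABETES)
      k <- match("diabetes", ctx$cm_names)
      cm_done[k] <- TRUE
      pending[EV_DIABETES] <- Inf
      cov[["diabetes"]] <- 1
      resched_cm(tE)
    } else if (j == EV_RELAPSE) {
      rec(tE, EV_RELAPSE)
      disease_stable <- FALSE
      pending[EV_RELAPSE] <- Inf
      pending[EV_REMISSION] <- tE + ctx$d_rem
      switched <- line < 3L && runif(1) < ctx$pi_switch
      if (switched || ctx$counts_wo_switch) failures <- failures + 1L
      if (switched) {
        target <- if (failures >= 2L) 3L else line + 1L
        if (on_tx) stop_tx()
        line <- target
        start_tx(seq_ids[target], tE)
      } else if (!on_tx && ctx$restart) {
        restart_pending <- TRUE
      }
    } else if (j == EV_REMISSION) {
      rec(tE, EV_REMISSION)
      disease_stable <- TRUE
      pending[EV_REMISSION] <- Inf
      if (restart_pending && !on_tx) {
        restart_pending <- FALSE
        start_tx(cur, tE)
      } else {
        sched_relapse(tE)
      }
    } else if (j == EV_DISCONT) {
      rec(tE, EV_DISCONT)
      stop_tx()
      sched_relapse(tE)
      resched_cm(tE)
    } else { # EV_TD
      rec(tE, EV_TD)
      td_done <- TRUE
      pending[EV_TD] <- Inf
    }
  }

  list(time = ev_t[seq_len(ne)], type = ev_y[seq_len(ne)],
       tx = ev_x[seq_len(ne)], flags = ev_f[seq_len(ne)])
}

## ---- user-facing simulation ---------------------------------------------

cohort_row_covariates <- function(cohort, i) {
  profile_covariates(list(
    age = cohort$age[i], sex = cohort$sex[i], bmi = cohort$bmi[i],
    total_chol = cohort$total_chol[i], hdl = cohort$hdl[i],
    trig = cohort$trig[i], glucose = cohort$glucose[i], sbp = cohort$sbp[i],
    smoking = cohort$smoking[i], antihypertensive = cohort$antihypertensive[i],
    prior_diabetes = cohort$prior_diabetes[i], prior_chd = cohort$prior_chd[i],
    prior_stroke = cohort$prior_stroke[i]))
}

raw_to_trajectory <- function(raw, ctx, patient, replication, sequence,
                              prior, adherence) {
  tx_name <- rep(NA_character_, length(raw$tx))
  tx_name[raw$tx > 0L] <- ctx$tx_names[raw$tx[raw$tx > 0L]]
  events <- data.frame(
    time = raw$time,
    type = ALL_EVENT_TYPES[raw$type],
    treatment = tx_name,
    flags = raw$flags)
  structure(list(patient = patient, replication = replication,
                 sequence = sequence, prior = prior, adherence = adherence,
                 events = events),
            class = "sz_trajectory")
}

#' @export
print.sz_trajectory <- function(x, ...) {
  cat("<sz_trajectory> patient ", x$patient, ", replication ",
      x$replication, ", sequence ", paste(x$sequence, collapse = " > "),
      "\n", sep = "")
  print(x$events)
  invisible(x)
}

#' Simulate one patient trajectory
#'
#' Runs the event loop for a single patient under a treatment sequence:
#' times to all candidate events are generated, the earliest occurs, state
#' is updated, and only clocks whose hazards changed are regenerated, until
#' death or the time horizon.
#'
#' @param profile a single-row cohort data frame or list of patient
#'   characteristics (see [generate_cohort()]).
#' @param sequence character vector of length 3: first-line, second-line,
#'   clozapine (see [enumerate_sequences()]).
#' @param p an `sz_params` object.
#' @param seed integer seed for this trajectory (substreams for background
#'   mortality and the event loop are derived from it).
#' @return an `sz_trajectory` object with an `events` data frame (columns
#'   `time`, `type`, `treatment`, `flags`).
#' @export
simulate_patient <- function(profile, sequence, p, seed = 1L) {
  ctx <- compile_model(p)
  seq_ids <- match(sequence, ctx$tx_names)
  if (anyNA(seq_ids))
    stop_config("unknown treatment(s) in sequence: ",
                paste(sequence[is.na(seq_ids)], collapse = ", "))
  profile <- as.list(profile)
  cov <- profile_covariates(profile)
  sex <- if (!is.null(profile$sex)) as.character(profile$sex)
         else if (cov[["male"]] == 1) "male" else "female"
  adherence <- as.character(profile$adherence %||% "full")
  raw <- sim_patient_raw(ctx, cov, sex, adherence, seq_ids,
                         seed_death = mix_seed(seed, PURPOSE_DEATH),
                         seed_traj = mix_seed(seed, PURPOSE_TRAJ))
  raw_to_trajectory(raw, ctx, profile$id %||% 1L, 1L, sequence,
                    prior = c(prior_chd = isTRUE(as.logical(profile$prior_chd)),
                              prior_stroke = isTRUE(as.logical(profile$prior_stroke)),
                              prior_diabetes = isTRUE(as.logical(profile$prior_diabetes))),
                    adherence = adherence)
}

#' Simulate a cohort under one treatment sequence
#'
#' Runs `n_patients x n_replications` trajectories. Replication `r` of
#' patient `i` uses RNG substreams keyed by `(seed, i, r)` only — not by the
#' sequence — so that, by default, baseline profiles, background mortality
#' and the shared portion of event draws are common random numbers across
#' treatment sequences (disable with `sim/common_random_numbers: false` in
#' the configuration, which keys the streams by the sequence as well).
#'
#' @param p an `sz_params` object.
#' @param sequence character vector of length 3.
#' @param cohort optional pre-generated cohort (defaults to a cohort of
#'   `n_patients` drawn from `p$baseline` under the seed).
#' @param n_patients,n_reps overrides for `p$sim$n_patients` /
#'   `p$sim$n_replications`.
#' @param seed master seed (defaults to `p$sim$master_seed`).
#' @param keep_trajectories return the trajectory objects (memory-heavy;
#'   default keeps only per-trajectory outcome summaries).
#' @return list with `summaries` (data frame, one row per trajectory, see
#'   [summarise_trajectory()]), `cohort`, and optionally `trajectories`.
#' @export
run_cohort <- function(p, sequence, cohort = NULL, n_patients = NULL,
                       n_reps = NULL, seed = NULL, keep_trajectories = FALSE) {
  seed <- seed %||% p$sim$master_seed
  n_patients <- n_patients %||% p$sim$n_patients
  n_reps <- n_reps %||% p$sim$n_replications
  ctx <- compile_model(p)
  octx <- compile_outcomes(p)
  seq_ids <- match(sequence, ctx$tx_names)
  if (anyNA(seq_ids))
    stop_config("unknown treatment(s) in sequence: ",
                paste(sequence[is.na(seq_ids)], collapse = ", "))
  if (is.null(cohort))
    cohort <- generate_cohort(p$baseline, n_patients,
                              seed = mix_seed(seed, PURPOSE_COHORT))
  n_patients <- nrow(cohort)
  crn <- p$sim$common_random_numbers
  seq_key <- if (crn) 0L else mix_seed(sequence)

  n_tot <- n_patients * n_reps
  sm <- matrix(0, nrow = n_tot, ncol = length(SUMMARY_COLS),
               dimnames = list(NULL, SUMMARY_COLS))
  trajs <- if (keep_trajectories) vector("list", n_tot)
  row <- 0L
  for (i in seq_len(n_patients)) {
    cov0 <- cohort_row_covariates(cohort, i)
    sex <- cohort$sex[i]
    adh <- cohort$adherence[i]
    prior <- c(prior_chd = cohort$prior_chd[i],
               prior_stroke = cohort$prior_stroke[i],
               prior_diabetes = cohort$prior_diabetes[i])
    for (r in seq_len(n_reps)) {
      row <- row + 1L
      raw <- sim_patient_raw(
        ctx, cov0, sex, adh, seq_ids,
        seed_death = mix_seed(seed, PURPOSE_DEATH, i, r, seq_key),
        seed_traj = mix_seed(seed, PURPOSE_TRAJ, i, r, seq_key))
      sm[row, ] <- summarise_raw(raw, octx, prior)
      if (keep_trajectories)
        trajs[[row]] <- raw_to_trajectory(raw, ctx, i, r, sequence, prior, adh)
    }
  }
  out <- list(summaries = as.data.frame(sm), cohort = cohort)
  if (keep_trajectories) out$trajectories <- trajs
  out
}
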