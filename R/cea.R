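## Health-economic analysis over first-line antipsychotics: aggregation,
## ICERs, net-monetary-benefit rankings, probabilistic and deterministic
## sensitivity analyses, scenarios.

#' Enumerate treatment sequences
#'
#' All ordered pairs of distinct first/second-line antipsychotics from the
#' candidate set, each closed by clozapine as the third and last line:
#' `n` candidates give `n * (n - 1)` sequences (90 for the ten first-line
#' antipsychotics).
#'
#' @param first_line_set character vector of distinct non-clozapine
#'   treatment names (>= 2).
#' @param clozapine name of the clozapine profile.
#' @return list of character vectors of length 3.
#' @export
enumerate_sequences <- function(first_line_set, clozapine = "clozapine") {
  if (anyDuplicated(first_line_set))
    stop_config("duplicate treatment names in first-line set")
  if (clozapine %in% first_line_set)
    stop_config("clozapine cannot be a first-line candidate")
  if (length(first_line_set) < 2L)
    stop_config("need at least two first-line candidates to form a second line")
  out <- list()
  for (i in first_line_set)
    for (j in setdiff(first_line_set, i))
      out[[length(out) + 1L]] <- c(i, j, clozapine)
  out
}

#' Net monetary benefit
#'
#' `NMB = QALYs x WTP - costs`; higher is better.
#'
#' @param qalys QALYs (vectorised).
#' @param costs costs in GBP.
#' @param wtp willingness to pay in GBP/QALY (>= 0).
#' @return NMB in GBP.
#' @export
net_monetary_benefit <- function(qalys, costs, wtp) {
  stopifnot(wtp >= 0)
  qalys * wtp - costs
}

first_line_of <- function(p) {
  names(p$treatments)[!vapply(p$treatments, `[[`, TRUE, "is_clozapine")]
}

clozapine_of <- function(p) {
  names(p$treatments)[vapply(p$treatments, `[[`, TRUE, "is_clozapine")]
}

## Mean outcome decomposition for the sequences sharing one first line,
## equally weighted across sequences (Monte-Carlo SEs for QALYs and costs).
run_first_line <- function(p, first, cohort, seed, n_reps, sequences) {
  seqs <- Filter(function(s) s[[1]] == first, sequences)
  means <- matrix(0, nrow = length(seqs), ncol = length(SUMMARY_COLS),
                  dimnames = list(NULL, SUMMARY_COLS))
  vq <- vc <- nn <- numeric(length(seqs))
  for (k in seq_along(seqs)) {
    res <- run_cohort(p, seqs[[k]], cohort = cohort, n_reps = n_reps,
                      seed = seed)
    sm <- res$summaries
    means[k, ] <- colMeans(sm)
    nn[k] <- nrow(sm)
    vq[k] <- stats::var(sm$qalys_discounted) / nn[k]
    vc[k] <- stats::var(sm$total_cost_discounted) / nn[k]
  }
  out <- colMeans(means)
  c(out, mcse_qalys = sqrt(sum(vq)) / length(seqs),
    mcse_cost = sqrt(sum(vc)) / length(seqs))
}

#' Run the base-case comparison of first-line antipsychotics
#'
#' Simulates every treatment sequence (each first-line candidate followed by
#' each remaining candidate, then clozapine), with one common baseline
#' cohort and common random numbers across sequences, and aggregates
#' outcomes per first-line treatment as the equally weighted mean over the
#' sequences sharing that first line.
#'
#' @param p an `sz_params` object.
#' @param seed master seed (defaults to `p$sim$master_seed`).
#' @param n_patients,n_reps cohort size and replications per patient
#'   (default `p$sim` values).
#' @param treatments optional subset of first-line candidates to compare.
#' @return an `sz_cea_result` data frame: one row per first-line treatment
#'   with the mean outcome decomposition, discounted QALYs and costs, and
#'   Monte-Carlo standard errors; the per-sequence means are in the
#'   `"sequence_means"` attribute.
#' @export
run_base_case <- function(p, seed = NULL, n_patients = NULL, n_reps = NULL,
                          treatments = NULL) {
  seed <- seed %||% p$sim$master_seed
  n_patients <- n_patients %||% p$sim$n_patients
  n_reps <- n_reps %||% p$sim$n_replications
  firsts <- treatments %||% first_line_of(p)
  stopifnot(all(firsts %in% first_line_of(p)))
  cloz <- clozapine_of(p)
  if (p$sim$starting_line == 2L) {
    ## evaluated drug taken as second line after one prior failure: the
    ## next switch goes straight to clozapine, so one sequence per drug
    pool <- first_line_of(p)
    sequences <- lapply(firsts, function(t)
      c(t, setdiff(pool, t)[1], cloz))
  } else {
    sequences <- enumerate_sequences(first_line_of(p), cloz)
    sequences <- Filter(function(s) s[[1]] %in% firsts, sequences)
  }
  cohort <- generate_cohort(p$baseline, n_patients,
                            seed = mix_seed(seed, PURPOSE_COHORT))
  rows <- lapply(firsts, function(f)
    run_first_line(p, f, cohort, seed, n_reps, sequences))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(treatment = firsts, out)
  rownames(out) <- NULL
  class(out) <- c("sz_cea_result", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_patients") <- n_patients
  attr(out, "n_reps") <- n_reps
  attr(out, "n_sequences") <- length(sequences)
  out
}

#' Pairwise incremental cost-effectiveness ratios
#'
#' For every pair of first-line treatments, using the lower-QALY arm as
#' reference: `ICER = (cost_high - cost_ref) / (QALY_high - QALY_ref)`.
#' Dominance (more QALYs at lower cost) is reported as a label rather than
#' a signed ratio; equal QALYs give an undefined ICER flag.
#'
#' @param results an `sz_cea_result` from [run_base_case()].
#' @return data frame with columns `reference`, `comparator`,
#'   `delta_qalys`, `delta_cost`, `icer`, `status`.
#' @export
icer_table <- function(results) {
  stopifnot(nrow(results) >= 2)
  cmb <- utils::combn(nrow(results), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (results$qalys_discounted[j] < results$qalys_discounted[i]) {
      tmp <- i; i <- j; j <- tmp
    } # i = reference (lower QALYs)
    dq <- results$qalys_discounted[j] - results$qalys_discounted[i]
    dc <- results$total_cost_discounted[j] - results$total_cost_discounted[i]
    if (dq == 0)
      data.frame(reference = results$treatment[i],
                 comparator = results$treatment[j],
                 delta_qalys = dq, delta_cost = dc, icer = NA_real_,
                 status = "undefined")
    else if (dc < 0)
      data.frame(reference = results$treatment[i],
                 comparator = results$treatment[j],
                 delta_qalys = dq, delta_cost = dc, icer = NA_real_,
                 status = "dominant")
    else
      data.frame(reference = results$treatment[i],
                 comparator = results$treatment[j],
                 delta_qalys = dq, delta_cost = dc, icer = dc / dq,
                 status = "icer")
  })
  do.call(rbind, rows)
}

#' Rank treatments by net monetary benefit across WTP thresholds
#'
#' Per willingness-to-pay value, treatments are sorted by descending NMB;
#' exact ties are broken by lower cost, then lexicographic name.
#'
#' @param results an `sz_cea_result`.
#' @param wtp_grid numeric vector of WTP thresholds (GBP/QALY).
#' @return long data frame: `wtp`, `treatment`, `qalys`, `cost`, `nmb`,
#'   `rank`.
#' @export
rank_treatments <- function(results, wtp_grid) {
  rows <- lapply(wtp_grid, function(w) {
    nmb <- net_monetary_benefit(results$qalys_discounted,
                                results$total_cost_discounted, w)
    ord <- order(-nmb, results$total_cost_discounted, results$treatment)
    data.frame(wtp = w, treatment = results$treatment[ord],
               qalys = results$qalys_discounted[ord],
               cost = results$total_cost_discounted[ord],
               nmb = nmb[ord], rank = seq_along(ord))
  })
  do.call(rbind, rows)
}

#' Probabilistic sensitivity analysis of the NMB ranking
#'
#' Redraws all uncertain parameters per draw, reruns the (reduced-size)
#' simulation, ranks first-line treatments by NMB at each WTP, and returns
#' rank-frequency matrices. By default each draw reuses the same run seed
#' (common random numbers across draws), so Monte-Carlo noise is common and
#' differences between draws are parameter-driven; all-fixed uncertainty
#' then gives a degenerate rank distribution.
#'
#' @param p an `sz_params` object with a populated uncertainty map.
#' @param n_draws number of PSA draws (default `p$sim$n_psa_draws`).
#' @param seed master seed.
#' @param n_patients,n_reps per-draw simulation size (default the
#'   `psa_n_patients` / `psa_n_reps` settings).
#' @param wtp_grid WTP thresholds (default `p$sim$base_wtp`).
#' @param independent_runs draw a fresh run seed per draw instead of common
#'   random numbers across draws.
#' @return an `sz_rank_distribution`: list with `wtps`, `prob` (list of
#'   treatment x rank probability matrices, one per WTP) and `n_draws`.
#' @export
run_psa <- function(p, n_draws = NULL, seed = NULL, n_patients = NULL,
                    n_reps = NULL, wtp_grid = NULL,
                    independent_runs = FALSE) {
  seed <- seed %||% p$sim$master_seed
  n_draws <- n_draws %||% p$sim$n_psa_draws
  n_patients <- n_patients %||% p$sim$psa_n_patients
  n_reps <- n_reps %||% p$sim$psa_n_reps
  wtp_grid <- wtp_grid %||% p$sim$base_wtp
  firsts <- first_line_of(p)
  nt <- length(firsts)
  counts <- lapply(wtp_grid, function(w)
    matrix(0, nt, nt, dimnames = list(treatment = firsts, rank = seq_len(nt))))
  names(counts) <- as.character(wtp_grid)
  for (d in seq_len(n_draws)) {
    pd <- draw_psa_parameter_set(p, seed = mix_seed(seed, PURPOSE_PSA, d))
    run_seed <- if (independent_runs) mix_seed(seed, PURPOSE_RUN, d)
                else mix_seed(seed, PURPOSE_RUN)
    res <- run_base_case(pd, seed = run_seed, n_patients = n_patients,
                         n_reps = n_reps)
    for (wi in seq_along(wtp_grid)) {
      rk <- rank_treatments(res, wtp_grid[wi])
      idx <- cbind(match(rk$treatment, firsts), rk$rank)
      counts[[wi]][idx] <- counts[[wi]][idx] + 1
    }
  }
  prob <- lapply(counts, function(m) m / n_draws)
  structure(list(wtps = wtp_grid, prob = prob, n_draws = n_draws),
            class = "sz_rank_distribution")
}

#' @export
print.sz_rank_distribution <- function(x, ...) {
  cat("<sz_rank_distribution> ", x$n_draws, " draws, WTP thresholds: ",
      paste(x$wtps, collapse = ", "), "\n", sep = "")
  print(round(x$prob[[1]], 3))
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado) for a treatment pair
#'
#' For each uncertain parameter, reruns the two first-line arms with the
#' parameter at its low and high value (2.5th/97.5th percentile of its PSA
#' distribution, or +/-20% for fixed quantities) while all other parameters
#' stay at base, under common random numbers, and records the incremental
#' NMB (arm A minus arm B) at the chosen WTP and the incremental QALYs.
#' Parameters without usable bounds (fixed at zero) are skipped with a
#' message.
#'
#' @param p an `sz_params` object.
#' @param pair character vector of two first-line treatment names
#'   (A vs B).
#' @param wtp willingness to pay (default `p$sim$base_wtp`).
#' @param seed master seed.
#' @param n_patients,n_reps simulation size per run (default PSA settings).
#' @return data frame sorted by decreasing swing: `path`, `low`, `high`,
#'   `inmb_low`, `inmb_high`, `iqaly_low`, `iqaly_high`, `swing`, plus the
#'   base-case values in attributes `inmb_base` / `iqaly_base`.
#' @export
run_dsa <- function(p, pair, wtp = NULL, seed = NULL, n_patients = NULL,
                    n_reps = NULL) {
  stopifnot(length(pair) == 2, all(pair %in% first_line_of(p)))
  wtp <- wtp %||% p$sim$base_wtp
  seed <- seed %||% p$sim$master_seed
  n_patients <- n_patients %||% p$sim$psa_n_patients
  n_reps <- n_reps %||% p$sim$psa_n_reps
  eval_pair <- function(pp) {
    res <- run_base_case(pp, seed = seed, n_patients = n_patients,
                         n_reps = n_reps, treatments = pair)
    i <- match(pair, res$treatment)
    nmb <- net_monetary_benefit(res$qalys_discounted,
                                res$total_cost_discounted, wtp)
    c(inmb = nmb[i[1]] - nmb[i[2]],
      iq = res$qalys_discounted[i[1]] - res$qalys_discounted[i[2]])
  }
  base <- eval_pair(p)
  rows <- list()
  for (q in p$uncertainty) {
    point <- param_get(p, q$path)
    if (identical(q$dist, "fixed")) {
      if (point == 0) { message("DSA: skipping ", q$path, " (fixed at 0)"); next }
      bounds <- c(0.8, 1.2) * point
    } else {
      bounds <- uq_quantile(q, c(0.025, 0.975))
    }
    lo <- eval_pair(param_set(p, q$path, bounds[1]))
    hi <- eval_pair(param_set(p, q$path, bounds[2]))
    rows[[length(rows) + 1L]] <- data.frame(
      path = q$path, low = bounds[1], high = bounds[2],
      inmb_low = lo[["inmb"]], inmb_high = hi[["inmb"]],
      iqaly_low = lo[["iq"]], iqaly_high = hi[["iq"]],
      swing = abs(hi[["inmb"]] - lo[["inmb"]]))
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "inmb_base") <- base[["inmb"]]
  attr(out, "iqaly_base") <- base[["iq"]]
  attr(out, "pair") <- pair
  attr(out, "wtp") <- wtp
  out
}

SCENARIO_AXES <- c("horizon", "annual_discount_rate", "starting_line",
                   "treatment_set")

#' Run a scenario analysis
#'
#' Reruns the base case under overridden scenario settings. Allowed axes:
#' `horizon` (years), `annual_discount_rate`, `starting_line` (2 = evaluate
#' the drugs as second-line treatment in non-first-episode schizophrenia:
#' patients start with one prior treatment failure and switch straight to
#' clozapine at the next failure) and `treatment_set` (character subset of
#' first-line candidates). Overriding any other field is an error.
#'
#' @param p an `sz_params` object.
#' @param scenario named list of overrides over the allowed axes.
#' @param seed,n_patients,n_reps as in [run_base_case()].
#' @return an `sz_cea_result` with a `"scenario"` attribute.
#' @export
run_scenario <- function(p, scenario, seed = NULL, n_patients = NULL,
                         n_reps = NULL) {
  bad <- setdiff(names(scenario), SCENARIO_AXES)
  if (length(bad))
    stop_config("not a scenario axis: ", paste(bad, collapse = ", "))
  p2 <- p
  if (!is.null(scenario$horizon)) p2$sim$horizon <- scenario$horizon
  if (!is.null(scenario$annual_discount_rate))
    p2$sim$annual_discount_rate <- scenario$annual_discount_rate
  if (!is.null(scenario$starting_line))
    p2$sim$starting_line <- as.integer(scenario$starting_line)
  out <- run_base_case(p2, seed = seed, n_patients = n_patients,
                       n_reps = n_reps, treatments = scenario$treatment_set)
  attr(out, "scenario") <- scenario
  out
}
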