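test_that("relapse times follow the modified exponential hazard", {
  p <- test_params()
  epi <- p$epidemiology   # untreated annual probability 0.45
  off <- list(disease_state = "stable", on_treatment = FALSE)
  # closed form: annual probability q gives rate -log(1-q); with q = 0.5 and
  # u = 0.5 the waiting time is exactly one year
  epi2 <- epi; epi2$annual_relapse_prob_no_treatment <- 0.5
  expect_equal(sample_time_to_relapse(off, epi2, u = 0.5), 1.0,
               tolerance = 1e-12)
  # RR = 1 on treatment is indistinguishable from off treatment
  tx1 <- p$treatments$alpha; tx1$relapse_risk_ratio <- 1
  on1 <- list(disease_state = "stable", on_treatment = TRUE, treatment = tx1,
              adherence = "full")
  for (u in c(0.1, 0.5, 0.9))
    expect_equal(sample_time_to_relapse(on1, epi, u = u),
                 sample_time_to_relapse(off, epi, u = u))
  # RR = 0.5 doubles the mean waiting time
  tx5 <- p$treatments$alpha
  on5 <- list(disease_state = "stable", on_treatment = TRUE, treatment = tx5,
              adherence = "full")
  set.seed(500)
  us <- runif(1e5)
  t_on <- vapply(us, function(u) sample_time_to_relapse(on5, epi, u = u), 0)
  t_off <- vapply(us, function(u) sample_time_to_relapse(off, epi, u = u), 0)
  expect_equal(mean(t_on) / mean(t_off), 2, tolerance = 1e-9)  # same uniforms
  expect_equal(mean(t_on), 2 / -log1p(-0.45), tolerance = 0.02)
  # partial adherence pulls the hazard multiplier half-way back to 1
  onp <- on5; onp$adherence <- "partial"
  expect_equal(sample_time_to_relapse(onp, epi, u = 0.5) /
                 sample_time_to_relapse(off, epi, u = 0.5),
               1 / 0.75, tolerance = 1e-9)
  # LAI forces full adherence regardless of the category
  lai <- list(disease_state = "stable", on_treatment = TRUE,
              treatment = p$treatments$beta, adherence = "none")
  expect_equal(sample_time_to_relapse(lai, epi, u = 0.5),
               sample_time_to_relapse(modifyList(lai, list(adherence = "full")),
                                      epi, u = 0.5))
  # contract: no relapse can be scheduled during a relapse episode
  expect_error(sample_time_to_relapse(list(disease_state = "relapse"), epi),
               "ongoing relapse")
})

test_that("remission is deterministic at relapse time + episode duration", {
  p <- test_params()
  expect_equal(schedule_remission(2.0, p$epidemiology), 2.5)
  expect_equal(schedule_remission(list(time = 9.8), p$epidemiology), 10.3)
})

test_that("discontinuation and tardive dyskinesia clocks are exponential", {
  p <- test_params()
  tx <- p$treatments$alpha
  tx$annual_discontinuation_prob <- 0
  expect_identical(sample_time_to_discontinuation(tx), Inf)
  tx$annual_discontinuation_prob <- 1 - exp(-1)   # rate exactly 1/year
  set.seed(501)
  ts <- vapply(runif(1e5), function(u) sample_time_to_discontinuation(tx, u = u), 0)
  expect_equal(mean(ts), 1, tolerance = 0.01)
  tx$annual_td_prob <- 0
  expect_identical(sample_time_to_td(tx), Inf)
  tx$annual_td_prob <- 0.05
  set.seed(502)
  ts <- vapply(runif(2e4), function(u) sample_time_to_td(tx, u = u), 0)
  expect_equal(mean(ts), 1 / -log1p(-0.05), tolerance = 0.02)
})

test_that("after discontinuation the relapse hazard reverts to the untreated level", {
  # engine cross-check: immediate certain discontinuation, then the observed
  # relapse waiting times must match the untreated exponential
  lst <- test_param_list()
  lst$treatments$alpha$annual_discontinuation_prob <- 1 - exp(-20) # ~instant
  lst$treatments$alpha$relapse_risk_ratio <- 0.01                  # strong effect while on
  lst$treatments$alpha$short_term_se_probs <- list()
  lst$epidemiology$switch_prob_after_relapse <- 0
  lst$epidemiology$restart_same_treatment_after_relapse <- FALSE
  lst$risk_models <- list()
  lst$life_table <- flat_life_table(q = 0)
  lst$sim$horizon <- 200
  p <- parameter_set(lst, quiet = TRUE)
  waits <- numeric(0)
  for (s in 1:400) {
    tr <- simulate_patient(test_profile(), c("alpha", "beta", "clozapine"), p,
                           seed = s)
    ev <- tr$events
    t_disc <- ev$time[ev$type == "discontinuation"][1]
    t_rel <- ev$time[ev$type == "relapse"][1]
    if (!is.na(t_disc) && !is.na(t_rel) && t_rel > t_disc)
      waits <- c(waits, t_rel - t_disc)
  }
  rate <- -log1p(-0.45)
  expect_gt(length(waits), 300)
  expect_gt(stats::ks.test(waits, stats::pexp, rate)$p.value, 0.01)
})

test_that("treatment start applies metabolic shifts and draws side-effects", {
  p <- test_params()
  st <- list(time = 0, profile = test_profile(), on_treatment = FALSE,
             tried = character(0))
  # all-zero profile changes nothing but the assignment
  tx0 <- p$treatments$alpha
  tx0$metabolic_deltas[] <- 0
  tx0$short_term_se_probs[] <- 0
  set.seed(503)
  res <- apply_treatment_start(st, tx0, p)
  expect_equal(res$state$profile, profile_covariates <- schizosim:::profile_covariates(test_profile()))
  expect_false(any(res$se_occurred))
  expect_true(res$state$on_treatment)
  expect_identical(res$state$tried, "alpha")
  # a glucose shift strictly increases subsequent diabetes risk
  txg <- p$treatments$alpha
  txg$metabolic_deltas[] <- 0
  txg$metabolic_deltas[["glucose"]] <- 0.5
  set.seed(504)
  res2 <- apply_treatment_start(st, txg, p)
  expect_gt(score_risk("diabetes", as.list(res2$state$profile), p$risk_models),
            score_risk("diabetes", test_profile(), p$risk_models))
  # starting a second treatment while one is active is a contract error
  expect_error(apply_treatment_start(res$state, p$treatments$beta, p),
               "while another is active")
  # sedation incidence matches its Bernoulli probability (binomial oracle)
  set.seed(505)
  n <- 1e5
  hits <- 0L
  for (i in seq_len(n)) {
    r <- apply_treatment_start(st, p$treatments$alpha, p)
    hits <- hits + r$se_occurred[["sedation"]]
  }
  expect_equal(hits / n, 0.2, tolerance = 0.004 / 0.2)
})

test_that("agranulocytosis occurs only under clozapine, with its fatality check", {
  p <- test_params()
  st <- list(time = 0, profile = test_profile(), on_treatment = FALSE,
             tried = character(0))
  cloz <- p$treatments$clozapine
  cloz$short_term_se_probs[["agranulocytosis"]] <- 1
  p2 <- p; p2$epidemiology$case_fatality[["agranulocytosis"]] <- 1
  set.seed(506)
  res <- apply_treatment_start(st, cloz, p2)
  expect_true(res$se_occurred[["agranulocytosis"]])
  expect_true(res$agran_fatal)
  # non-clozapine never draws agranulocytosis
  set.seed(507)
  res2 <- apply_treatment_start(st, p$treatments$alpha, p)
  expect_false(res2$se_occurred[["agranulocytosis"]])
})

test_that("relapse resolution: switch decision, failure counting, clozapine line", {
  p <- test_params()
  seqn <- c("alpha", "beta", "clozapine")
  st <- list(time = 1.5, line_index = 1L, consecutive_failures = 0L,
             disease_state = "stable", on_treatment = TRUE)
  # uniform draw below the switch probability -> switch to second line
  r <- resolve_relapse(st, seqn, p$epidemiology, u = 0.3)
  expect_true(r$switched)
  expect_identical(r$next_treatment, "beta")
  expect_identical(r$state$line_index, 2L)
  expect_identical(r$state$consecutive_failures, 1L)
  expect_identical(r$state$disease_state, "relapse")
  expect_equal(r$state$remission_time, 2.0)
  # draw above -> no switch, but the relapse still counts as a failure
  r2 <- resolve_relapse(st, seqn, p$epidemiology, u = 0.7)
  expect_false(r2$switched)
  expect_identical(r2$state$consecutive_failures, 1L)
  # with the counting flag off, a non-switching relapse does not count
  epi2 <- p$epidemiology; epi2$relapse_counts_without_switch <- FALSE
  r2b <- resolve_relapse(st, seqn, epi2, u = 0.7)
  expect_identical(r2b$state$consecutive_failures, 0L)
  # two consecutive failures -> the next switch goes to clozapine
  st2 <- modifyList(st, list(consecutive_failures = 1L))
  r3 <- resolve_relapse(st2, seqn, p$epidemiology, u = 0.1)
  expect_identical(r3$next_treatment, "clozapine")
  expect_identical(r3$state$line_index, 3L)
  # clozapine is absorbing: relapse never switches further
  st3 <- modifyList(st, list(line_index = 3L, consecutive_failures = 5L))
  r4 <- resolve_relapse(st3, seqn, p$epidemiology, u = 0.0001)
  expect_false(r4$switched)
  expect_null(r4$next_treatment)
  expect_equal(r4$state$remission_time, 2.0)
})

test_that("switch-probability boundaries: 0 never leaves first line, 1 always switches", {
  base <- test_param_list()
  base$risk_models <- list()
  base$life_table <- flat_life_table(q = 0)
  for (pi_switch in c(0, 1)) {
    lst <- base
    lst$epidemiology$switch_prob_after_relapse <- pi_switch
    p <- parameter_set(lst, quiet = TRUE)
    for (s in 1:30) {
      tr <- simulate_patient(test_profile(), c("alpha", "beta", "clozapine"),
                             p, seed = s)
      ev <- tr$events
      starts <- ev$treatment[ev$type == "treatment_start"]
      n_rel <- sum(ev$type == "relapse")
      if (pi_switch == 0) {
        expect_true(all(starts == "alpha"))
      } else if (n_rel > 0) {
        # every relapse is accompanied by a same-time switch (until clozapine)
        t_rel <- ev$time[ev$type == "relapse"]
        cloz_reached <- match("clozapine", starts)
        t_cloz <- ev$time[ev$type == "treatment_start"][cloz_reached]
        for (tt in t_rel)
          if (is.na(t_cloz) || tt <= t_cloz)
            expect_true(tt %in% ev$time[ev$type == "treatment_start"])
      }
    }
  }
})

test_that("a non-clozapine antipsychotic is never received twice across a trajectory", {
  p <- illustrative_params()
  seqs <- enumerate_sequences(names(p$treatments)[1:10][1:4])
  bad <- 0L
  for (s in 1:40) {
    tr <- simulate_patient(test_profile(), seqs[[(s %% 12) + 1]], p, seed = s)
    ev <- tr$events
    starts <- ev$treatment[ev$type == "treatment_start"]
    runs <- rle(starts)$values          # restarts of the same drug are allowed
    non_cloz <- runs[runs != "clozapine"]
    if (anyDuplicated(non_cloz)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})
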