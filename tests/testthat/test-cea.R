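make_results <- function(treatment, qalys, costs) {
  structure(data.frame(treatment = treatment, qalys_discounted = qalys,
                       total_cost_discounted = costs),
            class = c("sz_cea_result", "data.frame"))
}

test_that("sequence enumeration yields n(n-1) ordered pairs closed by clozapine", {
  s10 <- enumerate_sequences(paste0("t", 1:10))
  expect_length(s10, 90L)
  expect_true(all(vapply(s10, function(s) s[1] != s[2] &&
                           s[3] == "clozapine" &&
                           !"clozapine" %in% s[1:2], TRUE)))
  expect_identical(length(unique(vapply(s10, paste, "", collapse = "|"))), 90L)
  expect_length(enumerate_sequences(c("a", "b", "c")), 6L)
  expect_error(enumerate_sequences("a"), "at least two",
               class = "sz_config_error")
  expect_error(enumerate_sequences(c("a", "a", "b")), "duplicate",
               class = "sz_config_error")
  expect_error(enumerate_sequences(c("a", "clozapine")), "clozapine",
               class = "sz_config_error")
})

test_that("net monetary benefit arithmetic", {
  # worked micro-example: 6.121 QALYs, GBP 147,197, WTP GBP 20,000
  expect_equal(net_monetary_benefit(6.121, 147197, 20000), -24777)
  expect_equal(net_monetary_benefit(5, 1000, 0), -1000)
  # affine invariance: adding k QALYs everywhere shifts NMB by k * wtp
  q <- c(6.1, 6.0, 5.9); cc <- c(15e4, 16e4, 14e4)
  n0 <- net_monetary_benefit(q, cc, 20000)
  n1 <- net_monetary_benefit(q + 0.5, cc, 20000)
  expect_equal(n1 - n0, rep(0.5 * 20000, 3))
  expect_identical(order(n1), order(n0))
})

test_that("ICER table uses the lower-QALY arm as reference and flags dominance", {
  res <- make_results(c("a", "b", "c"), c(6.0, 6.1, 6.1), c(150000, 149900, 151000))
  tab <- icer_table(res)
  ab <- tab[tab$comparator == "b" & tab$reference == "a", ]
  expect_identical(ab$status, "dominant")      # more QALYs, lower cost
  ac <- tab[tab$comparator == "c" & tab$reference == "a", ]
  expect_identical(ac$status, "icer")
  expect_equal(ac$icer, (151000 - 150000) / 0.1, tolerance = 1e-9)
  bc <- tab[tab$reference %in% c("b", "c") & tab$comparator %in% c("b", "c"), ]
  expect_identical(bc$status, "undefined")     # identical QALYs
  expect_error(icer_table(res[1, ]))
})

test_that("NMB ranking: cost order at WTP 0, QALY order in the limit, crossover", {
  res <- make_results(c("a", "b", "c"), c(6.0, 6.2, 5.9),
                      c(150000, 155000, 149000))
  r0 <- rank_treatments(res, 0)
  expect_identical(r0$treatment, res$treatment[order(res$total_cost_discounted)])
  rinf <- rank_treatments(res, 1e9)
  expect_identical(rinf$treatment, res$treatment[order(-res$qalys_discounted)])
  # algebraic crossover: a vs b flip at dC/dQ = 5000/0.2 = 25000 GBP/QALY
  rlo <- rank_treatments(res, 24999)
  rhi <- rank_treatments(res, 25001)
  expect_lt(match("a", rlo$treatment), match("b", rlo$treatment))
  expect_gt(match("a", rhi$treatment), match("b", rhi$treatment))
  # deterministic tie-break: equal NMB resolved by lower cost then name
  tie <- make_results(c("y", "x"), c(6, 6), c(1000, 1000))
  expect_identical(rank_treatments(tie, 0)$treatment, c("x", "y"))
})

test_that("first-line aggregation is the equally weighted mean over its sequences", {
  p <- test_params()
  bc <- run_base_case(p, seed = 3, n_patients = 10, n_reps = 2)
  expect_identical(bc$treatment, c("alpha", "beta"))
  # independent recomputation straight from run_cohort
  cohort <- generate_cohort(p$baseline, 10,
                            seed = schizosim:::mix_seed(3, schizosim:::PURPOSE_COHORT))
  for (fl in c("alpha", "beta")) {
    other <- setdiff(c("alpha", "beta"), fl)
    res <- run_cohort(p, c(fl, other, "clozapine"), cohort = cohort,
                      n_reps = 2, seed = 3)
    expect_equal(bc$qalys_discounted[bc$treatment == fl],
                 mean(res$summaries$qalys_discounted), tolerance = 1e-12)
    expect_equal(bc$total_cost_discounted[bc$treatment == fl],
                 mean(res$summaries$total_cost_discounted), tolerance = 1e-9)
  }
})

test_that("PSA with all-fixed uncertainty degenerates to the deterministic ranking", {
  p <- test_params()
  p$uncertainty <- lapply(p$uncertainty, function(q) { q$dist <- "fixed"; q })
  rd <- run_psa(p, n_draws = 3, seed = 8)
  m <- rd$prob[[1]]
  expect_true(all(m %in% c(0, 1)))
  expect_true(all(rowSums(m) == 1) && all(colSums(m) == 1))
})

test_that("PSA rank matrices are doubly stochastic at any draw count", {
  p <- test_params()
  for (nd in c(1L, 7L)) {
    rd <- run_psa(p, n_draws = nd, seed = 15, wtp_grid = c(0, 20000))
    for (m in rd$prob) {
      expect_lt(max(abs(rowSums(m) - 1)), 1e-9)
      expect_lt(max(abs(colSums(m) - 1)), 1e-9)
    }
  }
})

test_that("PSA rank-1 probability matches the analytic flip probability", {
  # two treatments with identical clinical attributes; only A's drug cost is
  # uncertain. Under common random numbers the arms' event paths coincide,
  # so the ranking is decided purely by the drawn cost: P(B ranks first) =
  # P(drawn cost_A > cost_B), known in closed form from the gamma.
  lst <- test_param_list()
  lst$treatments$beta <- lst$treatments$alpha   # clone attributes
  lst$treatments$beta$annual_drug_cost <- 100
  lst$treatments$alpha$annual_drug_cost <- 100
  lst$risk_models <- list()
  lst$life_table <- flat_life_table(q = 0)
  lst$uncertainty <- list(list(path = "treatments/alpha/annual_drug_cost",
                               dist = "gamma", shape = 25, scale = 4))
  p <- parameter_set(lst, quiet = TRUE)
  n_draws <- 100L
  rd <- run_psa(p, n_draws = n_draws, seed = 300, n_patients = 10, n_reps = 1)
  p_beta_first <- rd$prob[[1]]["beta", 1]
  flip <- stats::pgamma(100, shape = 25, scale = 4, lower.tail = FALSE)
  expect_equal(p_beta_first, flip,
               tolerance = 4 * sqrt(flip * (1 - flip) / n_draws) / flip)
})

test_that("DSA: exact invariances under common random numbers, tornado ordering", {
  lst <- test_param_list()
  lst$treatments$clozapine$short_term_se_probs$agranulocytosis <- 0
  lst$risk_models <- list()
  lst$life_table <- flat_life_table(q = 0)   # death unreachable in horizon
  lst$uncertainty <- list(
    list(path = "treatments/alpha/annual_drug_cost", dist = "gamma",
         shape = 25, scale = 4),
    list(path = "costs/death_cost", dist = "fixed"),
    list(path = "treatments/alpha/relapse_risk_ratio", dist = "lognormal",
         meanlog = log(0.5), sdlog = 0.2))
  p <- parameter_set(lst, quiet = TRUE)
  tor <- run_dsa(p, c("alpha", "beta"), wtp = 20000, seed = 12,
                 n_patients = 15, n_reps = 1)
  expect_identical(tor$path[order(-tor$swing)], tor$path)
  rowc <- tor[tor$path == "treatments/alpha/annual_drug_cost", ]
  # drug cost perturbation: incremental QALYs untouched, exactly
  expect_identical(rowc$iqaly_low, attr(tor, "iqaly_base"))
  expect_identical(rowc$iqaly_high, attr(tor, "iqaly_base"))
  # and incremental NMB responds linearly: -(delta cost) x fixed exposure
  slope_lo <- (attr(tor, "inmb_base") - rowc$inmb_low) / (100 - rowc$low)
  slope_hi <- (rowc$inmb_high - attr(tor, "inmb_base")) / (rowc$high - 100)
  expect_equal(slope_lo, slope_hi, tolerance = 1e-9)
  # a parameter that cannot affect the pair has zero swing (death unreachable)
  rowd <- tor[tor$path == "costs/death_cost", ]
  expect_identical(rowd$swing, 0)
  # direction: a lower relapse risk ratio for A raises A's incremental QALYs
  rowr <- tor[tor$path == "treatments/alpha/relapse_risk_ratio", ]
  expect_gt(rowr$iqaly_low, rowr$iqaly_high)
})

test_that("DSA skips parameters without usable bounds, with a message", {
  p <- test_params()
  p$uncertainty <- list(list(path = "baseline/binary/prior_chd", dist = "fixed"))
  expect_message(
    tor <- run_dsa(p, c("alpha", "beta"), seed = 1, n_patients = 5, n_reps = 1),
    "skipping")
  expect_null(tor)
})

test_that("scenario overrides: horizon truncation, zero discounting, axis guard", {
  p <- test_params()
  s5 <- run_scenario(p, list(horizon = 5), seed = 4, n_patients = 10, n_reps = 1)
  expect_true(all(s5$life_years <= 5 + 1e-12))
  expect_true(all(s5$years_stable + s5$years_relapse <= 5 + 1e-9))
  s0 <- run_scenario(p, list(annual_discount_rate = 0), seed = 4,
                     n_patients = 10, n_reps = 1)
  expect_equal(s0$qalys_discounted, s0$qalys_undiscounted, tolerance = 1e-12)
  expect_error(run_scenario(p, list(u_stable = 0.9)), "not a scenario axis",
               class = "sz_config_error")
})

test_that("second-line scenario starts with one prior failure: next switch is clozapine", {
  p <- test_params()
  p$sim$starting_line <- 2L
  cloz_only_switches <- TRUE
  for (s in 1:25) {
    tr <- simulate_patient(test_profile(), c("alpha", "beta", "clozapine"), p,
                           seed = s)
    ev <- tr$events
    later <- ev$treatment[ev$type == "treatment_start" & ev$time > 0]
    if (any(!later %in% c("alpha", "clozapine"))) cloz_only_switches <- FALSE
  }
  expect_true(cloz_only_switches)
  sc <- run_scenario(test_params(), list(starting_line = 2), seed = 4,
                     n_patients = 10, n_reps = 1)
  expect_s3_class(sc, "sz_cea_result")
  expect_identical(attr(sc, "scenario")$starting_line, 2)
})
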