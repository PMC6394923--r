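test_that("median/hazard conversion and truncated means follow closed forms", {
  expect_equal(median_to_hazard(log(2)), 1)
  expect_equal(median_to_hazard(6.931), 0.1, tolerance = 1e-4)
  expect_error(median_to_hazard(0), "positive")
  # monthly death probability in (0, 1) for any positive hazard
  for (lam in c(1e-6, 0.05, 1, 20))
    expect_true(1 - exp(-lam) > 0 && 1 - exp(-lam) < 1)
  # discrete trace mean vs continuous truncated-exponential mean: half cycle
  lam <- median_to_hazard(12)
  expect_equal(truncated_mean(lam, 60), (1 / lam) * (1 - exp(-60 * lam)),
               tolerance = 0.5)
  # limits
  expect_lt(truncated_mean(50, 60), 1e-6)
  expect_equal(truncated_mean(1e-9, 60), 60, tolerance = 1e-4)
})

test_that("median calibration inverts the truncated trace mean", {
  for (x in c(10.86, 23.72, 35.05)) {
    m <- calibrate_median(x, 60)
    expect_equal(truncated_mean(median_to_hazard(m), 60), x, tolerance = 1e-6)
  }
  # near-horizon target still converges to a very large median
  m <- calibrate_median(59.99, 60, tol = 1e-6)
  expect_gt(m, 1000)
  expect_equal(truncated_mean(median_to_hazard(m), 60), 59.99, tolerance = 1e-4)
  expect_error(calibrate_median(60, 60), "infeasible")
  # the trace mean is monotone in the median (bisection is well posed)
  ms <- c(5, 10, 20, 40, 80)
  means <- vapply(ms, function(m) truncated_mean(median_to_hazard(m), 60), 1)
  expect_true(all(diff(means) > 0))
})

test_that("cohort traces conserve occupancy and score utilities correctly", {
  cfg <- baseline_config()
  spec <- markov_spec(median = 14, horizon = 60,
                      schedule = data.frame(phase = c("on_chemoradiotherapy",
                                                      "surgical_recovery",
                                                      "stable_disease"),
                                            cycles = c(3L, 1L, NA)))
  tr <- run_cohort_trace(spec, cfg$utilities)
  occ <- tr$alive_disease_free + tr$alive_with_disease + tr$dead
  expect_equal(occ, rep(1, 60), tolerance = 1e-9)
  expect_true(all(diff(tr$dead) >= -1e-12))
  expect_true(all(diff(tr$qalm_cum) <= diff(tr$lm_cum) + 1e-12))
  # all utilities 1 makes QALM = LM exactly
  ones <- utility_table(stats::setNames(rep(1, 6),
    c("stable_disease", "on_chemoradiotherapy", "chemo_toxicity",
      "surgical_recovery", "surgical_complication", "unresectable")))
  tr1 <- run_cohort_trace(spec, ones)
  expect_equal(attr(tr1, "qalm"), attr(tr1, "lm"), tolerance = 1e-12)
  # a huge hazard leaves essentially only the first cycle
  trh <- run_cohort_trace(markov_spec(lambda = 20, horizon = 60), cfg$utilities)
  expect_lt(abs(attr(trh, "lm") - exp(-20)), 1e-12)
  # unknown phase in the schedule is fatal
  bad <- markov_spec(median = 14, schedule = data.frame(phase = "nosuch",
                                                        cycles = NA_integer_))
  expect_error(run_cohort_trace(bad, cfg$utilities), "unknown health phase")
})

test_that("a constant 0.65 utility reproduces the unresectable-cohort QALM", {
  cfg <- baseline_config()
  spec <- markov_spec(median = calibrate_median(10.86, 60), horizon = 60,
                      schedule = data.frame(phase = "unresectable",
                                            cycles = NA_integer_),
                      start_state = "alive_with_disease")
  tr <- run_cohort_trace(spec, cfg$utilities)
  expect_equal(attr(tr, "lm"), 10.86, tolerance = 1e-6)
  expect_equal(attr(tr, "qalm"), 0.65 * 10.86, tolerance = 1e-6)
})

test_that("the decision tree carries the published branch probabilities", {
  cfg <- baseline_config()
  tree <- build_decision_tree(cfg$params, cfg$cohort_payoffs)
  sf_probs <- vapply(tree$sf$children, `[[`, 1, "prob")
  expect_equal(sf_probs, c(0.94, 0.06), tolerance = 1e-12)
  nat_probs <- vapply(tree$nat$children, `[[`, 1, "prob")
  expect_equal(nat_probs, c(0.41, 0.10, 0.49), tolerance = 1e-12)
  # every chance node's children sum to one (rollup enforces this)
  expect_silent(expected_value_rollup(tree))
  # degenerate parameters leave a single effective path
  cfg2 <- apply_override(cfg, "nat.p_explore", 0)
  cfg2 <- apply_override(cfg2, "nat.p_resect", 1)
  cfg2 <- apply_override(cfg2, "nat.p_poc5", 0)
  cfg2 <- apply_override(cfg2, "nat.p_r0", 1)
  cfg2 <- apply_override(cfg2, "nat.p_poc34", 0)
  ev <- evaluate_model(cfg2)
  expect_equal(itt(ev$summary, "NAT", "life_months"), 35.05, tolerance = 1e-9)
  expect_equal(itt(ev$summary, "NAT", "qalms"), 29.87, tolerance = 1e-9)
})

test_that("rollup is linear and consistent with the cohort table", {
  cfg <- baseline_config()
  ev <- evaluate_model(cfg)
  # ITT expectation equals the probability-weighted sum over terminal cohorts
  for (strat in c("SF", "NAT")) {
    tab <- ev$cohorts[ev$cohorts$strategy == strat, ]
    expect_equal(sum(tab$probability), 1, tolerance = 1e-9)
    expect_equal(sum(tab$probability * tab$life_months),
                 itt(ev$summary, strat, "life_months"), tolerance = 1e-9)
    expect_equal(sum(tab$probability * tab$qalm_mixed),
                 itt(ev$summary, strat, "qalms"), tolerance = 1e-9)
  }
  # scaling all payoffs scales the expectations
  ev3 <- evaluate_model(scale_payoffs(cfg, 3))
  expect_equal(ev3$summary$life_months, 3 * ev$summary$life_months,
               tolerance = 1e-9)
  expect_equal(ev3$summary$qalms, 3 * ev$summary$qalms, tolerance = 1e-9)
  # QALM never exceeds LM for any cohort
  expect_true(all(ev$cohorts$qalm_mixed <= ev$cohorts$life_months + 1e-9))
  # an empty tree gives an empty table
  expect_equal(nrow(cohort_table(NULL)), 0L)
})

test_that("raising a leaf payoff or a better branch's probability helps", {
  cfg <- baseline_config()
  base <- evaluate_model(cfg)$summary
  up <- cfg
  up$cohort_payoffs$nat_r0 <- cohort_payoff("up", 40,
    cfg$cohort_payoffs$nat_r0$qalms)
  expect_gt(itt(evaluate_model(up)$summary, "NAT", "life_months"),
            itt(base, "NAT", "life_months"))
  # shifting probability toward the better sibling (resection) raises NAT
  more <- apply_override(cfg, "nat.p_resect", 0.5)
  expect_gt(itt(evaluate_model(more)$summary, "NAT", "qalms"),
            itt(base, "NAT", "qalms"))
})

test_that("trace mode reproduces direct-mode life months after calibration", {
  cfg <- baseline_config()
  direct <- evaluate_model(cfg, mode = "direct")
  trace <- evaluate_model(cfg, mode = "trace")
  dd <- direct$cohorts[order(direct$cohorts$cohort), ]
  tt <- trace$cohorts[order(trace$cohorts$cohort), ]
  expect_equal(tt$life_months, dd$life_months, tolerance = 1e-5)
  expect_equal(tt$probability, dd$probability, tolerance = 1e-12)
  # trace-mode QALMs are schedule-derived, but still bounded by life months
  expect_true(all(tt$qalm_mixed <= tt$life_months + 1e-9))
  expect_equal(itt(trace$summary, "SF", "life_months"),
               itt(direct$summary, "SF", "life_months"), tolerance = 1e-5)
})
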