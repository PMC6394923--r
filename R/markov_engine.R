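#' @title Decision tree and Markov cohort engine
#' @name markov_engine
#' @description
#' The model compares two strategies for potentially resectable pancreatic
#' cancer. Surgery-first (SF): attempted resection (with operative-mortality
#' risk), margin status R0/R1, then adjuvant therapy received or not.
#' Neoadjuvant therapy (NAT): chemo/chemoradiotherapy, then resection,
#' exploratory surgery only, or no surgery. Each terminal cohort carries a
#' payoff in life-months and QALMs, either taken directly from published
#' cohort results ("direct" mode) or generated by a monthly three-state
#' Markov trace (alive disease-free, alive with disease, dead) under a
#' constant exponential hazard with a phase-based utility schedule ("trace"
#' mode). Strategy-level results are intention-to-treat expectations rolled
#' up through the chance nodes.
#'
#' Two conventions are load-bearing and fixed throughout: the R0 probability
#' is conditional on resection, and a fatal (grade 5) post-operative
#' complication accrues zero life-months. Grade 3-4 complications and grade
#' 3+ toxicities alter only the QALM payoff (via variant mixing), never
#' survival.
NULL

#' Convert a median survival to a monthly exponential hazard
#'
#' @param median Median survival in months (> 0).
#' @return Hazard rate per month, `ln(2) / median`.
#' @export
median_to_hazard <- function(median) {
  if (any(!is.finite(median)) || any(median <= 0))
    stop("median must be positive and finite")
  log(2) / median
}

#' Expected months alive within a finite horizon
#'
#' Discrete-trace expectation under a constant monthly hazard: the sum over
#' cycles of the end-of-cycle survival probability,
#' `sum_{t=1..H} exp(-lambda t)`. Converges to the continuous truncated
#' exponential mean `(1/lambda)(1 - exp(-lambda H))` to within half a cycle.
#'
#' @param lambda Monthly hazard (> 0).
#' @param horizon Number of monthly cycles (>= 1).
#' @return Expected life-months within the horizon.
#' @export
truncated_mean <- function(lambda, horizon) {
  if (lambda <= 0) stop("lambda must be positive")
  if (horizon < 1) stop("horizon must be at least 1 cycle")
  sum(exp(-lambda * seq_len(horizon)))
}

#' Find the median whose truncated trace mean matches a target
#'
#' Inverts [truncated_mean()] by bisection so that published cohort
#' life-month payoffs (which are horizon-truncated means) can parameterise
#' the exponential survival of a Markov trace.
#'
#' @param target_mean Target expected life-months, `0 < target < horizon`.
#' @param horizon Cycles (default 60).
#' @param tol Absolute tolerance on the achieved mean.
#' @return Median survival in months.
#' @export
calibrate_median <- function(target_mean, horizon = 60, tol = 1e-8) {
  if (target_mean <= 0) stop("target_mean must be positive")
  if (target_mean >= horizon)
    stop("target mean ", target_mean, " is infeasible: the truncated mean ",
         "cannot reach the horizon of ", horizon, " months")
  f <- function(m) truncated_mean(median_to_hazard(m), horizon) - target_mean
  lo <- 1e-9; hi <- 2 * target_mean
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e12) stop("failed to bracket the target mean")
  }
  while (hi - lo > max(tol * 1e-3, 1e-12) && abs(f((lo + hi) / 2)) > 0) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' Specify a Markov cohort trace
#'
#' @param median Median survival in months (alternative to `lambda`).
#' @param lambda Monthly hazard (alternative to `median`).
#' @param horizon Cycles (default 60).
#' @param schedule `data.frame` with columns `phase` (a health phase named in
#'   the utility table) and `cycles` (non-negative integer, or `NA` meaning
#'   "all remaining cycles"). Defaults to stable disease throughout.
#' @param start_state `"alive_disease_free"` or `"alive_with_disease"`; the
#'   two alive states carry the same utility weight and are distinguished
#'   only in the trace occupancy.
#' @return An object of class `markov_spec`.
#' @export
markov_spec <- function(median = NULL, lambda = NULL, horizon = 60,
                        schedule = NULL,
                        start_state = c("alive_disease_free",
                                        "alive_with_disease")) {
  if (is.null(lambda)) {
    if (is.null(median)) stop("supply either median or lambda")
    lambda <- median_to_hazard(median)
  }
  if (lambda <= 0) stop("lambda must be positive")
  if (horizon < 1) stop("horizon must be at least 1")
  if (is.null(schedule))
    schedule <- data.frame(phase = "stable_disease", cycles = NA_integer_)
  stopifnot(is.data.frame(schedule), all(c("phase", "cycles") %in% names(schedule)))
  if (any(!is.na(schedule$cycles) & schedule$cycles < 0))
    stop("schedule durations must be non-negative")
  structure(list(lambda = lambda, horizon = as.integer(horizon),
                 schedule = schedule, start_state = match.arg(start_state)),
            class = "markov_spec")
}

# expand a phase schedule into one utility value per cycle
schedule_utilities <- function(schedule, utilities, horizon) {
  unknown <- setdiff(schedule$phase, names(utilities))
  if (length(unknown))
    stop("schedule references unknown health phase(s): ",
         paste(unknown, collapse = ", "))
  u <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    len <- schedule$cycles[i]
    if (is.na(len)) len <- max(horizon - length(u), 0)
    u <- c(u, rep(utilities[[schedule$phase[i]]], len))
  }
  if (length(u) < horizon)  # pad with the final phase
    u <- c(u, rep(u[length(u)], horizon - length(u)))
  u[seq_len(horizon)]
}

#' Run a Markov cohort trace
#'
#' Applies the monthly death probability `1 - exp(-lambda)` cycle by cycle
#' and accumulates life-months (sum of alive occupancy) and QALMs (alive
#' occupancy weighted by the scheduled phase utility).
#'
#' @param spec A [markov_spec()].
#' @param utilities A [utility_table()].
#' @return A `data.frame` of class `cohort_trace` with per-cycle occupancy
#'   (`alive_disease_free`, `alive_with_disease`, `dead`), cumulative
#'   `lm_cum` and `qalm_cum`; totals in attributes `lm` and `qalm`.
#' @export
run_cohort_trace <- function(spec, utilities) {
  stopifnot(inherits(spec, "markov_spec"))
  H <- spec$horizon
  u <- schedule_utilities(spec$schedule, utilities, H)
  surv <- exp(-spec$lambda * seq_len(H))
  free <- if (spec$start_state == "alive_disease_free") surv else rep(0, H)
  withd <- surv - free
  trace <- data.frame(cycle = seq_len(H),
                      alive_disease_free = free,
                      alive_with_disease = withd,
                      dead = 1 - surv,
                      utility = u,
                      lm_cum = cumsum(surv),
                      qalm_cum = cumsum(surv * u))
  structure(trace, class = c("cohort_trace", "data.frame"),
            lm = sum(surv), qalm = sum(surv * u))
}

# ---------------------------------------------------------------------------
# Decision tree

new_node <- function(label, children = NULL, payoff = NULL) {
  structure(list(label = label, children = children, payoff = payoff),
            class = "cohort_node")
}

# expectation of the QALM payoff over the complication/toxicity variants:
# POC (grade 3-4 post-operative complication) with probability p_poc and
# AT (grade 3+ adjuvant toxicity) with probability p_at, independent.
mix_qalm <- function(qalms, p_poc = 0, p_at = 0) {
  g <- function(nm, fallback) if (nm %in% names(qalms)) qalms[[nm]] else fallback
  base <- qalms[["baseline"]]
  poc  <- g("POC", base)
  at   <- g("AT", base)
  both <- g("POC_AT", base - (base - poc) - (base - at))
  (1 - p_poc) * (1 - p_at) * base + p_poc * (1 - p_at) * poc +
    (1 - p_poc) * p_at * at + p_poc * p_at * both
}

leaf_node <- function(label, payoff, p_poc = 0, p_at = 0) {
  stopifnot(inherits(payoff, "cohort_payoff"))
  new_node(label, payoff = list(
    lm = payoff$life_months,
    qalm = mix_qalm(payoff$qalms, p_poc, p_at),
    qalms = payoff$qalms,
    mix = c(poc = p_poc, at = p_at),
    cohort = label))
}

death_leaf <- function() new_node("operative death (grade 5)",
                                  payoff = list(lm = 0, qalm = 0,
                                                qalms = c(baseline = 0),
                                                mix = c(poc = 0, at = 0),
                                                cohort = "operative_death"))

pt <- function(params, arm, nm) params[[arm]][[nm]]$point

#' Build the two-strategy decision tree
#'
#' Assembles the SF and NAT chance-node trees from transition probabilities
#' and terminal cohort payoffs. Residual branch masses are computed here:
#' the NAT no-surgery branch is `1 - p_resect - p_explore` and the SF
#' exploratory branch is `1 - p_resect`; a negative residual is an error.
#' R0/R1 split is conditional on surviving resection; grade 5 operative
#' mortality leads to a zero payoff. QALM payoffs at resection leaves are
#' mixed over complication (probability `p_poc34`) and, in the SF adjuvant
#' arms, adjuvant-toxicity (probability `p_adj_tox3`) variants.
#'
#' @param params A [pathway_params()].
#' @param payoffs Named list of [cohort_payoff()] covering the nine cohort
#'   keys (`nat_r0`, `nat_r1`, `nat_explore`, `nat_no_surgery`, `sf_r0_adj`,
#'   `sf_r0_no_adj`, `sf_r1_adj`, `sf_r1_no_adj`, `sf_explore`).
#' @return An object of class `decision_tree` with elements `sf` and `nat`.
#' @export
build_decision_tree <- function(params, payoffs) {
  stopifnot(inherits(params, "pathway_params"))
  miss <- setdiff(COHORT_KEYS, names(payoffs))
  if (length(miss)) stop("payoffs missing cohort(s): ", paste(miss, collapse = ", "))

  branch <- function(prob, node) list(prob = prob, node = node)

  # SF subtree: resect -> {grade-5 death | survive -> R0/R1 -> adjuvant y/n};
  # exploratory surgery absorbs 1 - p_resect
  poc_sf <- pt(params, "sf", "p_poc34"); at_sf <- pt(params, "sf", "p_adj_tox3")
  p_adj <- pt(params, "sf", "p_adjuvant")
  sf_resid <- 1 - pt(params, "sf", "p_resect")
  if (sf_resid < -1e-9) stop("SF exploratory residual branch is negative")
  sf_r0 <- new_node("R0", children = list(
    branch(p_adj, leaf_node("sf_r0_adj", payoffs$sf_r0_adj, poc_sf, at_sf)),
    branch(1 - p_adj, leaf_node("sf_r0_no_adj", payoffs$sf_r0_no_adj, poc_sf))))
  sf_r1 <- new_node("R1", children = list(
    branch(p_adj, leaf_node("sf_r1_adj", payoffs$sf_r1_adj, poc_sf, at_sf)),
    branch(1 - p_adj, leaf_node("sf_r1_no_adj", payoffs$sf_r1_no_adj, poc_sf))))
  sf_survive <- new_node("survives surgery", children = list(
    branch(pt(params, "sf", "p_r0"), sf_r0),
    branch(1 - pt(params, "sf", "p_r0"), sf_r1)))
  sf_resect <- new_node("resection", children = list(
    branch(pt(params, "sf", "p_poc5"), death_leaf()),
    branch(1 - pt(params, "sf", "p_poc5"), sf_survive)))
  sf <- new_node("SF", children = list(
    branch(pt(params, "sf", "p_resect"), sf_resect),
    branch(max(sf_resid, 0), leaf_node("sf_explore", payoffs$sf_explore))))

  # NAT subtree: resect -> {grade-5 death | survive -> R0/R1}; exploratory
  # surgery at its own probability; no surgery absorbs the residual
  poc_nat <- pt(params, "nat", "p_poc34")
  nat_resid <- 1 - pt(params, "nat", "p_resect") - pt(params, "nat", "p_explore")
  if (nat_resid < -1e-9)
    stop("NAT no-surgery residual branch is negative: resection + ",
         "exploratory probabilities exceed 1")
  nat_survive <- new_node("survives surgery", children = list(
    branch(pt(params, "nat", "p_r0"), leaf_node("nat_r0", payoffs$nat_r0, poc_nat)),
    branch(1 - pt(params, "nat", "p_r0"), leaf_node("nat_r1", payoffs$nat_r1, poc_nat))))
  nat_resect <- new_node("resection", children = list(
    branch(pt(params, "nat", "p_poc5"), death_leaf()),
    branch(1 - pt(params, "nat", "p_poc5"), nat_survive)))
  nat <- new_node("NAT", children = list(
    branch(pt(params, "nat", "p_resect"), nat_resect),
    branch(pt(params, "nat", "p_explore"), leaf_node("nat_explore", payoffs$nat_explore)),
    branch(max(nat_resid, 0), leaf_node("nat_no_surgery", payoffs$nat_no_surgery))))

  structure(list(sf = sf, nat = nat), class = "decision_tree")
}

node_ev <- function(node) {
  if (!is.null(node$payoff))
    return(c(lm = node$payoff$lm, qalm = node$payoff$qalm))
  if (is.null(node$children)) stop("unresolved leaf '", node$label,
                                   "': no payoff and no children")
  probs <- vapply(node$children, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("child probabilities at node '", node$label, "' sum to ",
         sum(probs), ", not 1")
  vals <- vapply(node$children, function(ch) node_ev(ch$node), numeric(2))
  c(lm = sum(probs * vals["lm", ]), qalm = sum(probs * vals["qalm", ]))
}

#' Roll up intention-to-treat expectations
#'
#' Probability-weighted expectation from the leaves to each strategy root,
#' separately for life-months and QALMs.
#'
#' @param tree A [build_decision_tree()] result.
#' @return A `data.frame` of class `outcome_summary` with one row per
#'   strategy (`SF`, `NAT`) and columns `life_months`, `qalms`; the
#'   incremental SF minus NAT differences are stored in
#'   `attr(, "incremental")`.
#' @export
expected_value_rollup <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  sf <- node_ev(tree$sf); nat <- node_ev(tree$nat)
  out <- data.frame(strategy = c("SF", "NAT"),
                    life_months = c(sf[["lm"]], nat[["lm"]]),
                    qalms = c(sf[["qalm"]], nat[["qalm"]]))
  structure(out, class = c("outcome_summary", "data.frame"),
            incremental = c(life_months = sf[["lm"]] - nat[["lm"]],
                            qalms = sf[["qalm"]] - nat[["qalm"]]))
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("Intention-to-treat expectations:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-4s %6.2f life-months  %6.2f QALMs\n",
                x$strategy[i], x$life_months[i], x$qalms[i]))
  inc <- attr(x, "incremental")
  cat(sprintf("  SF - NAT: %+.2f life-months, %+.2f QALMs\n",
              inc[["life_months"]], inc[["qalms"]]))
  invisible(x)
}

collect_leaves <- function(node, prob = 1) {
  if (!is.null(node$payoff)) {
    p <- node$payoff
    g <- function(nm) if (nm %in% names(p$qalms)) p$qalms[[nm]] else NA_real_
    return(data.frame(cohort = p$cohort, probability = prob,
                      life_months = p$lm,
                      qalm_baseline = g("baseline"), qalm_POC = g("POC"),
                      qalm_AT = g("AT"), qalm_POC_AT = g("POC_AT"),
                      qalm_mixed = p$qalm))
  }
  do.call(rbind, lapply(node$children, function(ch)
    collect_leaves(ch$node, prob * ch$prob)))
}

#' Tabulate per-cohort results
#'
#' One row per terminal cohort of each strategy: the path probability of
#' reaching the cohort, its life-months, its QALM variants and the
#' variant-mixed QALM actually used in the rollup.
#'
#' @param tree A [build_decision_tree()] result (or `NULL` for an empty
#'   table).
#' @return A `data.frame` with a `strategy` column.
#' @export
cohort_table <- function(tree) {
  if (is.null(tree))
    return(data.frame(strategy = character(), cohort = character(),
                      probability = numeric(), life_months = numeric(),
                      qalm_baseline = numeric(), qalm_POC = numeric(),
                      qalm_AT = numeric(), qalm_POC_AT = numeric(),
                      qalm_mixed = numeric()))
  stopifnot(inherits(tree, "decision_tree"))
  sf <- collect_leaves(tree$sf); sf$strategy <- "SF"
  nat <- collect_leaves(tree$nat); nat$strategy <- "NAT"
  out <- rbind(sf, nat)
  out[, c("strategy", setdiff(names(out), "strategy"))]
}

# ---------------------------------------------------------------------------
# Trace-mode payoffs

# default utility schedules per cohort and payoff variant; the phases mirror
# the treatment trajectory: neoadjuvant phase 3 cycles, surgical recovery 1
# cycle, adjuvant phase 6 cycles, stable disease thereafter; unresectable
# cohorts remain at the pre-operative quality of life throughout.
default_schedules <- function(cohort) {
  sched <- function(...) {
    ph <- list(...)
    data.frame(phase = vapply(ph, `[[`, "", 1),
               cycles = vapply(ph, function(p) as.integer(p[[2]]), 1L))
  }
  rest <- function(phase) data.frame(phase = phase, cycles = NA_integer_)
  stable <- rest("stable_disease")
  switch(cohort,
    nat_r0 = ,
    nat_r1 = list(
      baseline = rbind(sched(list("on_chemoradiotherapy", 3),
                             list("surgical_recovery", 1)), stable),
      POC = rbind(sched(list("on_chemoradiotherapy", 3),
                        list("surgical_complication", 1)), stable)),
    sf_r0_adj = ,
    sf_r1_adj = list(
      baseline = rbind(sched(list("surgical_recovery", 1),
                             list("on_chemoradiotherapy", 6)), stable),
      POC = rbind(sched(list("surgical_complication", 1),
                        list("on_chemoradiotherapy", 6)), stable),
      AT = rbind(sched(list("surgical_recovery", 1),
                       list("chemo_toxicity", 6)), stable),
      POC_AT = rbind(sched(list("surgical_complication", 1),
                           list("chemo_toxicity", 6)), stable)),
    sf_r0_no_adj = ,
    sf_r1_no_adj = list(
      baseline = rbind(sched(list("surgical_recovery", 1)), stable),
      POC = rbind(sched(list("surgical_complication", 1)), stable)),
    nat_explore = ,
    sf_explore = ,
    nat_no_surgery = list(baseline = rest("unresectable")),
    stop("no default schedule for cohort ", cohort))
}

#' Generate trace-mode cohort payoffs
#'
#' For each cohort, calibrates an exponential median so the truncated Markov
#' trace reproduces the cohort's life-months, then scores QALM variants by
#' running the trace under each variant's utility schedule. Resected cohorts
#' start disease-free; unresectable cohorts start in the with-disease state.
#'
#' @param config A `model_config`; the cohort life-month targets are taken
#'   from its `cohort_payoffs`.
#' @param horizon Cycles (default 60).
#' @return Named list of [cohort_payoff()] computed from traces.
#' @export
trace_payoffs <- function(config, horizon = 60) {
  out <- list()
  for (key in COHORT_KEYS) {
    target <- config$cohort_payoffs[[key]]$life_months
    med <- calibrate_median(target, horizon)
    start <- if (grepl("explore|no_surgery", key)) "alive_with_disease"
             else "alive_disease_free"
    schedules <- default_schedules(key)
    qalms <- vapply(schedules, function(s) {
      spec <- markov_spec(median = med, horizon = horizon, schedule = s,
                          start_state = start)
      attr(run_cohort_trace(spec, config$utilities), "qalm")
    }, numeric(1))
    lm <- attr(run_cohort_trace(
      markov_spec(median = med, horizon = horizon,
                  schedule = schedules$baseline, start_state = start),
      config$utilities), "lm")
    out[[key]] <- cohort_payoff(key, lm, qalms)
  }
  out
}

#' Evaluate the model end to end
#'
#' Builds the decision tree and rolls up intention-to-treat expectations, in
#' either evaluation mode.
#'
#' @param config A `model_config` from [load_config()].
#' @param mode `"direct"` scores terminal cohorts with the configured payoff
#'   table; `"trace"` re-derives every payoff from a calibrated Markov trace
#'   with the default utility schedules.
#' @param horizon Cycles for trace mode (default 60).
#' @return List of class `model_evaluation`: `summary`
#'   ([expected_value_rollup()] result), `cohorts` ([cohort_table()]),
#'   `tree`, `mode`.
#' @export
evaluate_model <- function(config, mode = c("direct", "trace"), horizon = 60) {
  stopifnot(inherits(config, "model_config"))
  mode <- match.arg(mode)
  payoffs <- if (mode == "direct") config$cohort_payoffs
             else trace_payoffs(config, horizon)
  tree <- build_decision_tree(config$params, payoffs)
  structure(list(summary = expected_value_rollup(tree),
                 cohorts = cohort_table(tree),
                 tree = tree, mode = mode),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("Model evaluation (", x$mode, " mode)\n", sep = "")
  print(x$summary)
  invisible(x)
}
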