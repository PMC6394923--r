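#' @title Model parameters: domain types, validation and file I/O
#' @name parameters
#' @description
#' The decision model is driven by three kinds of inputs: per-pathway
#' transition probabilities with their uncertainty (point estimate, 95% CI,
#' reported range, standard deviation and a fitted parametric distribution),
#' the utility weights that convert life-months into quality-adjusted
#' life-months (QALMs), and the per-cohort terminal payoffs used in
#' direct-payoff evaluation. This file defines the constructors and
#' validators for those types and the YAML/CSV readers and writers.
NULL

# health phases recognised by the utility table; the dead state is implicitly 0
UTILITY_PHASES <- c("stable_disease", "on_chemoradiotherapy", "chemo_toxicity",
                    "surgical_recovery", "surgical_complication", "unresectable")

# parameter slots per pathway, in the fixed declared order used for sampling
NAT_PARAMS <- c("p_tox3", "p_resect", "p_explore", "p_r0", "p_poc34", "p_poc5")
SF_PARAMS  <- c("p_resect", "p_r0", "p_poc34", "p_poc5", "p_adjuvant", "p_adj_tox3")

# cohort keys expected in a payoff block
COHORT_KEYS <- c("nat_r0", "nat_r1", "nat_explore", "nat_no_surgery",
                 "sf_r0_adj", "sf_r0_no_adj", "sf_r1_adj", "sf_r1_no_adj",
                 "sf_explore")

#' Create a proportion estimate with uncertainty
#'
#' Bundles a transition probability's point estimate with its 95% confidence
#' interval, the lowest/highest values reported across source studies, its
#' standard deviation, and (optionally) a fitted parametric distribution used
#' for probabilistic sensitivity analysis.
#'
#' @param point Point estimate, a probability in \[0, 1\].
#' @param ci Length-2 numeric, 95% CI; must bracket `point`.
#' @param range Length-2 numeric, lowest and highest reported values.
#' @param sd Non-negative standard deviation of the estimate.
#' @param distribution Optional [distribution_spec()].
#' @return An object of class `proportion_estimate`.
#' @export
proportion_estimate <- function(point, ci = c(point, point),
                                range = c(0, 1), sd = 0,
                                distribution = NULL) {
  stopifnot(is.numeric(point), length(point) == 1L,
            length(ci) == 2L, length(range) == 2L)
  if (is.na(point) || point < 0 || point > 1)
    stop("point estimate must be a probability in [0, 1], got ", point)
  if (any(ci < 0) || any(ci > 1) || ci[1] > ci[2])
    stop("confidence interval must be ordered probabilities, got [",
         ci[1], ", ", ci[2], "]")
  if (ci[1] > point || ci[2] < point)
    stop("confidence interval [", ci[1], ", ", ci[2],
         "] does not bracket the point estimate ", point)
  if (range[1] > range[2])
    stop("range must be ordered, got [", range[1], ", ", range[2], "]")
  if (sd < 0) stop("sd must be non-negative")
  if (!is.null(distribution) && !inherits(distribution, "distribution_spec"))
    stop("distribution must be a distribution_spec or NULL")
  structure(list(point = point, ci_low = ci[1], ci_high = ci[2],
                 range_low = range[1], range_high = range[2],
                 sd = sd, variance = sd^2, distribution = distribution),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%.4g (95%% CI %.4g-%.4g; range %.4g-%.4g; sd %.4g)\n",
              x$point, x$ci_low, x$ci_high, x$range_low, x$range_high, x$sd))
  if (!is.null(x$distribution)) {
    cat("  distribution: "); print(x$distribution)
  }
  invisible(x)
}

#' Utility weights per health phase
#'
#' Utility weights scale each month survived from 0 (death) to 1 (full
#' health). The six phases distinguished by the model are stable disease,
#' receiving chemo/chemoradiotherapy, chemo/radiotherapy toxicity, surgical
#' recovery, surgical complications, and living with unresectable disease.
#'
#' @param ... Named utilities, or a single named numeric vector/list.
#' @return Named numeric vector of class `utility_table`.
#' @export
utility_table <- function(...) {
  u <- c(...)
  if (is.list(u)) u <- unlist(u)
  if (is.null(names(u)) || any(names(u) == ""))
    stop("all utilities must be named")
  unknown <- setdiff(names(u), UTILITY_PHASES)
  if (length(unknown))
    stop("unknown health phase(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(UTILITY_PHASES, names(u))
  if (length(missing))
    stop("missing utilities for phase(s): ", paste(missing, collapse = ", "))
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]")
  structure(u[UTILITY_PHASES], class = "utility_table")
}

#' Terminal cohort payoff
#'
#' A cohort's cumulative expected life-months together with its QALM payoff
#' variants. `baseline` is the uncomplicated QALM; `POC`, `AT` and `POC_AT`
#' are the variants under grade 3-4 post-operative complications, grade 3+
#' adjuvant toxicity, and both. Variants not applicable to a cohort are
#' omitted.
#'
#' @param label Human-readable cohort label.
#' @param life_months Expected life-months, non-negative.
#' @param qalms Named numeric of QALM variants; must contain `baseline`.
#' @return An object of class `cohort_payoff`.
#' @export
cohort_payoff <- function(label, life_months, qalms) {
  qalms <- unlist(qalms)
  stopifnot(is.numeric(life_months), length(life_months) == 1L)
  if (life_months < 0) stop("life_months must be non-negative")
  if (!("baseline" %in% names(qalms)))
    stop("qalms must contain a 'baseline' entry")
  bad <- setdiff(names(qalms), c("baseline", "POC", "AT", "POC_AT"))
  if (length(bad)) stop("unknown QALM variant(s): ", paste(bad, collapse = ", "))
  if (any(qalms < 0)) stop("QALMs must be non-negative")
  if (qalms[["baseline"]] > life_months + 1e-9)
    stop("baseline QALM (", qalms[["baseline"]],
         ") exceeds life months (", life_months, ") for cohort ", label)
  if (any(qalms > qalms[["baseline"]] + 1e-9))
    stop("variant QALMs may not exceed the baseline QALM for cohort ", label)
  structure(list(label = label, life_months = life_months, qalms = qalms),
            class = "cohort_payoff")
}

#' Per-pathway transition probabilities
#'
#' Holds one [proportion_estimate()] per transition probability for both
#' strategies. For the neoadjuvant (NAT) pathway: grade 3+ neoadjuvant
#' toxicity, resection, exploratory surgery, R0 resection (conditional on
#' resection), grade 3-4 and grade 5 post-operative complications. For the
#' surgery-first (SF) pathway: resection, R0 (conditional), grade 3-4 and
#' grade 5 complications, receipt of adjuvant therapy, and grade 3+ adjuvant
#' toxicity. Residual branch masses are implicit: NAT no-surgery is
#' `1 - p_resect - p_explore`; SF exploratory surgery is `1 - p_resect`.
#'
#' @param nat,sf Named lists of [proportion_estimate()] objects covering the
#'   slots above (bare probabilities are promoted).
#' @return An object of class `pathway_params`.
#' @export
pathway_params <- function(nat, sf) {
  promote <- function(lst) lapply(lst, function(p) {
    if (inherits(p, "proportion_estimate")) p else proportion_estimate(p)
  })
  nat <- promote(nat); sf <- promote(sf)
  miss_n <- setdiff(NAT_PARAMS, names(nat))
  miss_s <- setdiff(SF_PARAMS, names(sf))
  if (length(miss_n)) stop("NAT parameters missing: ", paste(miss_n, collapse = ", "))
  if (length(miss_s)) stop("SF parameters missing: ", paste(miss_s, collapse = ", "))
  obj <- structure(list(nat = nat[NAT_PARAMS], sf = sf[SF_PARAMS]),
                   class = "pathway_params")
  validate_pathway_params(obj)
  obj
}

validate_pathway_params <- function(params) {
  resid_nat <- 1 - params$nat$p_resect$point - params$nat$p_explore$point
  if (resid_nat < -1e-9)
    stop("NAT resection (", params$nat$p_resect$point, ") + exploratory (",
         params$nat$p_explore$point, ") exceed 1; the no-surgery branch ",
         "would be negative")
  invisible(params)
}

#' @export
print.pathway_params <- function(x, ...) {
  for (arm in c("nat", "sf")) {
    cat(toupper(arm), "pathway:\n")
    for (nm in names(x[[arm]]))
      cat(sprintf("  %-11s %.4g\n", nm, x[[arm]][[nm]]$point))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# YAML configuration

parse_prop <- function(node, path) {
  need <- function(cond, what)
    if (!cond) stop("config field ", path, ": ", what)
  need(!is.null(node$point), "missing 'point'")
  dist <- NULL
  if (!is.null(node$distribution)) {
    d <- node$distribution
    need(!is.null(d$family), "distribution missing 'family'")
    dist <- distribution_spec(d$family, unlist(d$params), ad_stat = d$ad_stat)
  }
  tryCatch(
    proportion_estimate(
      point = node$point,
      ci = if (is.null(node$ci)) c(node$point, node$point) else unlist(node$ci),
      range = if (is.null(node$range)) c(0, 1) else unlist(node$range),
      sd = if (is.null(node$sd)) 0 else node$sd,
      distribution = dist),
    error = function(e) stop("config field ", path, ": ", conditionMessage(e),
                             call. = FALSE))
}

parse_payoff <- function(node, key) {
  tryCatch(
    cohort_payoff(label = if (is.null(node$label)) key else node$label,
                  life_months = node$life_months,
                  qalms = unlist(node$qalms)),
    error = function(e) stop("config cohort_payoffs.", key, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Load a model configuration from YAML
#'
#' Reads and validates the full model input set: per-pathway transition
#' probabilities (with CI, range, sd and fitted distribution), the utility
#' table, and the per-cohort payoffs. The bundled transcription of the
#' published inputs is available via
#' `system.file("extdata", "baseline.yaml", package = "pdacmarkov")`.
#'
#' @param path Path to a YAML file with top-level keys `nat`, `sf`,
#'   `utilities` and `cohort_payoffs`.
#' @return A list of class `model_config` with elements `params`
#'   ([pathway_params()]), `utilities` ([utility_table()]) and
#'   `cohort_payoffs` (named list of [cohort_payoff()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (key in c("nat", "sf", "utilities", "cohort_payoffs"))
    if (is.null(raw[[key]])) stop("config missing top-level key '", key, "'")
  nat <- lapply(stats::setNames(nm = names(raw$nat)), function(nm)
    parse_prop(raw$nat[[nm]], paste0("nat.", nm)))
  sf <- lapply(stats::setNames(nm = names(raw$sf)), function(nm)
    parse_prop(raw$sf[[nm]], paste0("sf.", nm)))
  payoffs <- lapply(stats::setNames(nm = names(raw$cohort_payoffs)), function(k)
    parse_payoff(raw$cohort_payoffs[[k]], k))
  miss <- setdiff(COHORT_KEYS, names(payoffs))
  if (length(miss))
    stop("config cohort_payoffs missing: ", paste(miss, collapse = ", "))
  structure(list(params = pathway_params(nat, sf),
                 utilities = utility_table(raw$utilities),
                 cohort_payoffs = payoffs),
            class = "model_config")
}

#' Save a model configuration to YAML
#'
#' Inverse of [load_config()]; the round trip is lossless to the numeric
#' precision of the YAML representation.
#'
#' @param config A `model_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  ser_prop <- function(p) {
    out <- list(point = p$point, ci = c(p$ci_low, p$ci_high),
                range = c(p$range_low, p$range_high), sd = p$sd)
    if (!is.null(p$distribution))
      out$distribution <- list(family = p$distribution$family,
                               params = as.list(p$distribution$params),
                               ad_stat = p$distribution$ad_stat)
    out
  }
  ser_payoff <- function(cp)
    list(label = cp$label, life_months = cp$life_months,
         qalms = as.list(cp$qalms))
  raw <- list(nat = lapply(config$params$nat, ser_prop),
              sf = lapply(config$params$sf, ser_prop),
              utilities = as.list(unclass(config$utilities)),
              cohort_payoffs = lapply(config$cohort_payoffs, ser_payoff))
  yaml::write_yaml(raw, path, precision = 12)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Study records

#' Load trial-arm study records from CSV
#'
#' Reads a literature-pool table with one row per trial arm. Required
#' columns: `study_id`, `pathway` (NAT or SF), `design` (RCT, phase2 or
#' cohort) and `n`. Optional: any number of `events_<outcome>` count columns,
#' `median_os` and `median_dfs` (months). Event counts are validated against
#' `n` row by row. The bundled transcription of the included-trials table is
#' at `system.file("extdata", "studies.csv", package = "pdacmarkov")`.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, header row mandatory).
#' @return A `data.frame` of class `study_records`.
#' @export
load_study_records <- function(path) {
  if (!file.exists(path)) stop("study record file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("study record file ", path, " contains no rows")
    return(structure(df, class = c("study_records", "data.frame")))
  }
  req <- c("study_id", "pathway", "design", "n")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("study record file missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$pathway %in% c("NAT", "SF")))
    stop("pathway must be 'NAT' or 'SF'")
  if (!all(df$design %in% c("RCT", "phase2", "cohort")))
    stop("design must be one of 'RCT', 'phase2', 'cohort'")
  if (any(is.na(df$n)) || any(df$n <= 0) || any(df$n != round(df$n)))
    stop("n must be a positive integer for every row")
  for (col in grep("^events_", names(df), value = TRUE)) {
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < 0 | df[[col]] > df$n | df[[col]] != round(df[[col]])))
    if (length(bad))
      stop("column ", col, ": event count invalid (exceeds n or negative) ",
           "in row(s) ", paste(bad, collapse = ", "),
           " (study ", paste(df$study_id[bad], collapse = ", "), ")")
  }
  for (col in intersect(c("median_os", "median_dfs"), names(df))) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] <= 0 | !is.finite(df[[col]])))
    if (length(bad))
      stop("column ", col, ": must be finite and positive; bad row(s) ",
           paste(bad, collapse = ", "))
  }
  structure(df, class = c("study_records", "data.frame"))
}
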