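#' @title Probabilistic sensitivity analysis
#' @name psa
#' @description
#' Monte Carlo propagation of parameter uncertainty: every transition
#' probability is drawn from its uncertainty distribution, residual branches
#' are re-balanced, both strategies are re-evaluated in direct-payoff mode,
#' and the per-iteration expectations are summarised (mean, range, sd,
#' variance, win and indifference frequencies).
#'
#' Three sampling interpretations are provided because the published
#' description of the uncertainty distributions is not self-consistent (see
#' the methods vignette):
#' \describe{
#'   \item{`"range"` (default)}{uniform between the lowest and highest value
#'     reported across source studies -- the same extremes the deterministic
#'     analysis sweeps.}
#'   \item{`"beta"`}{a beta distribution moment-matched to the point
#'     estimate and standard deviation, truncated to the reported range.
#'     Because both rollups are multilinear in the probabilities, this mode's
#'     Monte Carlo mean reproduces the baseline rollup (up to truncation
#'     effects); it propagates the quoted standard deviations.}
#'   \item{`"table2"`}{the literal fitted parametric distributions attached
#'     to each parameter, clamped to \[0, 1\].}
#' }
NULL

# fixed declared sampling order; streams are stable across runs
PSA_PARAM_IDS <- c(paste0("nat.", NAT_PARAMS), paste0("sf.", SF_PARAMS))

sample_param <- function(p, n, mode) {
  lo <- p$range_low; hi <- p$range_high
  switch(mode,
    range = {
      if (hi <= lo) rep(p$point, n) else stats::runif(n, lo, hi)
    },
    beta = {
      m <- p$point; v <- p$variance
      if (v <= 0) return(rep(m, n))
      nu <- m * (1 - m) / v - 1
      if (nu <= 0) {
        warning("sd too large for a beta distribution at point ", m,
                "; falling back to uniform over the reported range")
        return(stats::runif(n, lo, hi))
      }
      a <- m * nu; b <- (1 - m) * nu
      u <- stats::runif(n, stats::pbeta(lo, a, b), stats::pbeta(hi, a, b))
      stats::qbeta(u, a, b)
    },
    table2 = {
      if (is.null(p$distribution)) rep(p$point, n)
      else dist_quantile(p$distribution, stats::runif(n))
    })
}

# vectorised direct-payoff evaluation of both strategies over parameter draws
psa_evaluate <- function(d, payoffs) {
  q <- function(key) payoffs[[key]]$qalms
  lm <- function(key) payoffs[[key]]$life_months

  sf_r0a <- mix_qalm(q("sf_r0_adj"), d[["sf.p_poc34"]], d[["sf.p_adj_tox3"]])
  sf_r0n <- mix_qalm(q("sf_r0_no_adj"), d[["sf.p_poc34"]])
  sf_r1a <- mix_qalm(q("sf_r1_adj"), d[["sf.p_poc34"]], d[["sf.p_adj_tox3"]])
  sf_r1n <- mix_qalm(q("sf_r1_no_adj"), d[["sf.p_poc34"]])
  p_adj <- d[["sf.p_adjuvant"]]; p_r0s <- d[["sf.p_r0"]]
  res_lm <- p_r0s * (p_adj * lm("sf_r0_adj") + (1 - p_adj) * lm("sf_r0_no_adj")) +
    (1 - p_r0s) * (p_adj * lm("sf_r1_adj") + (1 - p_adj) * lm("sf_r1_no_adj"))
  res_q <- p_r0s * (p_adj * sf_r0a + (1 - p_adj) * sf_r0n) +
    (1 - p_r0s) * (p_adj * sf_r1a + (1 - p_adj) * sf_r1n)
  sf_lm <- d[["sf.p_resect"]] * (1 - d[["sf.p_poc5"]]) * res_lm +
    (1 - d[["sf.p_resect"]]) * lm("sf_explore")
  sf_qalm <- d[["sf.p_resect"]] * (1 - d[["sf.p_poc5"]]) * res_q +
    (1 - d[["sf.p_resect"]]) * q("sf_explore")[["baseline"]]

  nat_r0 <- mix_qalm(q("nat_r0"), d[["nat.p_poc34"]])
  nat_r1 <- mix_qalm(q("nat_r1"), d[["nat.p_poc34"]])
  p_r0n <- d[["nat.p_r0"]]
  p_ns <- 1 - d[["nat.p_resect"]] - d[["nat.p_explore"]]
  nat_lm <- d[["nat.p_resect"]] * (1 - d[["nat.p_poc5"]]) *
    (p_r0n * lm("nat_r0") + (1 - p_r0n) * lm("nat_r1")) +
    d[["nat.p_explore"]] * lm("nat_explore") + p_ns * lm("nat_no_surgery")
  nat_qalm <- d[["nat.p_resect"]] * (1 - d[["nat.p_poc5"]]) *
    (p_r0n * nat_r0 + (1 - p_r0n) * nat_r1) +
    d[["nat.p_explore"]] * q("nat_explore")[["baseline"]] +
    p_ns * q("nat_no_surgery")[["baseline"]]

  data.frame(sf_lm = sf_lm, sf_qalm = sf_qalm,
             nat_lm = nat_lm, nat_qalm = nat_qalm)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every transition probability `n_iter` times (in a fixed declared
#' parameter order, so the random stream is stable), clamps draws to
#' \[0, 1\], re-balances the NAT branch masses when a drawn resection plus
#' exploratory probability exceeds one (both are scaled down
#' proportionally, leaving no-surgery mass zero), and re-evaluates both
#' strategies per iteration in direct-payoff mode. Survival payoffs are held
#' at baseline; only probabilities are sampled.
#'
#' @param config A `model_config`.
#' @param n_iter Iterations (default 10000).
#' @param seed Optional integer seed; the run is fully reproducible given
#'   the seed.
#' @param mode Sampling mode: `"range"` (default), `"beta"` or `"table2"`.
#' @return An object of class `psa_result`: `values` (per-iteration
#'   `data.frame` with `sf_lm`, `sf_qalm`, `nat_lm`, `nat_qalm`), `draws`
#'   (per-iteration parameter values after clamping/re-balancing), `summary`
#'   (mean/min/max/sd/variance per strategy and measure), plus `n_iter`,
#'   `seed`, `mode`.
#' @export
run_psa <- function(config, n_iter = 10000, seed = NULL,
                    mode = c("range", "beta", "table2")) {
  stopifnot(inherits(config, "model_config"))
  mode <- match.arg(mode)
  if (n_iter < 1) stop("n_iter must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  draws <- list()
  for (id in PSA_PARAM_IDS) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    p <- config$params[[parts[1]]][[parts[2]]]
    x <- sample_param(p, n_iter, mode)
    n_clamped <- sum(x < 0 | x > 1)
    if (n_clamped > 0.01 * n_iter)
      warning(sprintf("parameter %s: %d of %d draws (%.1f%%) clamped to [0, 1]",
                      id, n_clamped, n_iter, 100 * n_clamped / n_iter))
    draws[[id]] <- pmin(pmax(x, 0), 1)
  }
  draws <- as.data.frame(draws, check.names = FALSE)

  s <- draws[["nat.p_resect"]] + draws[["nat.p_explore"]]
  over <- s > 1
  if (any(over)) {
    draws[["nat.p_resect"]][over] <- draws[["nat.p_resect"]][over] / s[over]
    draws[["nat.p_explore"]][over] <- draws[["nat.p_explore"]][over] / s[over]
  }

  values <- psa_evaluate(draws, config$cohort_payoffs)
  summarise <- function(v) c(mean = mean(v), min = min(v), max = max(v),
                             sd = stats::sd(v), variance = stats::var(v))
  summ <- as.data.frame(t(vapply(values, summarise, numeric(5))))
  summ <- cbind(measure = rownames(summ), summ)
  rownames(summ) <- NULL

  structure(list(values = values, draws = draws, summary = summ,
                 n_iter = n_iter, seed = seed, mode = mode,
                 n_rebalanced = sum(over)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations, mode '%s'%s\n", x$n_iter, x$mode,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s mean %6.2f  range %6.2f-%6.2f  sd %5.2f\n",
                x$summary$measure[i], x$summary$mean[i], x$summary$min[i],
                x$summary$max[i], x$summary$sd[i]))
  invisible(x)
}

#' Pathway-selection frequencies under a minimum significant difference
#'
#' Classifies every PSA iteration by the paired strategy difference: SF win,
#' NAT win, or indifference when the absolute difference is below the
#' minimum significant difference (MSD).
#'
#' @param result A [run_psa()] result.
#' @param msd Minimum significant difference in months (default 3.65).
#' @param objective `"life_months"` (default) or `"qalms"`.
#' @return List with `indifference`, `win_sf`, `win_nat` (proportions
#'   summing to 1) and `msd`.
#' @export
indifference_rate <- function(result, msd = 3.65,
                              objective = c("life_months", "qalms")) {
  stopifnot(inherits(result, "psa_result"))
  objective <- match.arg(objective)
  if (msd < 0) stop("msd must be non-negative")
  d <- if (objective == "life_months")
    result$values$sf_lm - result$values$nat_lm
  else result$values$sf_qalm - result$values$nat_qalm
  ind <- abs(d) < msd
  list(indifference = mean(ind),
       win_sf = mean(!ind & d > 0),
       win_nat = mean(!ind & d < 0),
       msd = msd, objective = objective)
}
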