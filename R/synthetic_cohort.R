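#' @title Synthetic literature pools with known ground truth
#' @name synthetic_cohort
#' @description
#' Generates trial pools that emulate the structure of the source
#' literature: per-study sample sizes over a realistic spread, binomial
#' outcome counts around true proportions with between-study heterogeneity
#' injected on the double-arcsine scale (the same scale the pooling model
#' assumes, so recovery experiments are internally consistent), and
#' per-study median survivals distributed as the sampling distribution of a
#' sample median of exponential lifetimes. Everything is reproducible from a
#' seed, which makes the pooling and rollup machinery testable end to end
#' without any external data.
NULL

#' Configure a synthetic literature pool
#'
#' @param k_studies Number of studies (default 50, the size of the
#'   neoadjuvant evidence base the model draws on).
#' @param n_range Length-2 integer, min/max patients per study (default
#'   c(11, 121), the smallest and largest source trials).
#' @param true_props Named vector of true outcome proportions; one
#'   `events_<name>` column is generated per entry.
#' @param tau Between-study heterogeneity (sd on the double-arcsine scale,
#'   radians; default 0.05).
#' @param true_median True median overall survival in months (default 17).
#' @param pathway,design Labels stamped on the generated records.
#' @param exact_medians If `TRUE`, study medians are simulated as the exact
#'   median of `n` exponential lifetimes; otherwise (default) the asymptotic
#'   normal approximation of the sample median is used.
#' @param seed Optional integer seed applied by [generate_study_pool()].
#' @return A list of class `synthetic_pool_config`.
#' @export
synthetic_pool_config <- function(k_studies = 50, n_range = c(11, 121),
                                  true_props = c(resect = 0.41),
                                  tau = 0.05, true_median = 17,
                                  pathway = "NAT", design = "phase2",
                                  exact_medians = FALSE, seed = NULL) {
  stopifnot(k_studies >= 1, length(n_range) == 2L, n_range[1] >= 1,
            n_range[1] <= n_range[2])
  if (is.null(names(true_props)) || any(names(true_props) == ""))
    stop("true_props must be named")
  if (any(true_props < 0 | true_props > 1))
    stop("true proportions must lie in [0, 1]")
  if (tau < 0) stop("tau must be non-negative")
  if (true_median <= 0) stop("true_median must be positive")
  structure(list(k_studies = as.integer(k_studies),
                 n_range = as.integer(n_range),
                 true_props = true_props, tau = tau,
                 true_median = true_median, pathway = pathway,
                 design = design, exact_medians = exact_medians,
                 seed = seed),
            class = "synthetic_pool_config")
}

#' Generate one synthetic study pool
#'
#' Per study: `n` is uniform over `n_range`; for each outcome, a study-level
#' proportion is drawn on the arcsine-square-root scale with sd `tau` around
#' the truth and back-transformed, then the event count is binomial; the
#' study median survival is drawn from the sampling distribution of the
#' median of `n` exponential lifetimes with the configured true median.
#'
#' @param cfg A [synthetic_pool_config()].
#' @param seed Seed override; defaults to `cfg$seed` (use `NULL` inside a
#'   larger seeded simulation to avoid resetting the RNG).
#' @return A `study_records` data frame.
#' @export
generate_study_pool <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_pool_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$k_studies
  # sample.int avoids sample()'s scalar-x expansion when the range collapses
  n <- cfg$n_range[1] +
    sample.int(cfg$n_range[2] - cfg$n_range[1] + 1L, k, replace = TRUE) - 1L
  df <- data.frame(study_id = sprintf("sim_%03d", seq_len(k)),
                   pathway = cfg$pathway, design = cfg$design, n = n)
  for (nm in names(cfg$true_props)) {
    t_true <- asin(sqrt(cfg$true_props[[nm]]))
    t_i <- stats::rnorm(k, t_true, cfg$tau)
    p_i <- sin(pmin(pmax(t_i, 0), pi / 2))^2
    df[[paste0("events_", nm)]] <- stats::rbinom(k, n, p_i)
  }
  lambda <- log(2) / cfg$true_median
  if (cfg$exact_medians) {
    df$median_os <- vapply(n, function(ni)
      stats::median(stats::rexp(ni, lambda)), numeric(1))
  } else {
    # asymptotic sd of the sample median of n exponentials: 1/(lambda sqrt(n))
    df$median_os <- pmax(stats::rnorm(k, cfg$true_median,
                                      1 / (lambda * sqrt(n))), 0.1)
  }
  structure(df, class = c("study_records", "data.frame"))
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a pool and re-estimates every configured proportion
#' ([pool_proportions()]) and the median survival ([pooled_median()]),
#' reporting mean estimate, bias and 95% CI coverage against the known
#' truth.
#'
#' @param cfg A [synthetic_pool_config()].
#' @param replicates Number of replicate pools (>= 1).
#' @return A `data.frame` with one row per parameter: `parameter`, `truth`,
#'   `mean_estimate`, `bias`, `coverage` (NA for the pooled median, which
#'   has no CI).
#' @export
recovery_experiment <- function(cfg, replicates) {
  stopifnot(inherits(cfg, "synthetic_pool_config"), replicates >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nms <- names(cfg$true_props)
  est <- matrix(NA_real_, replicates, length(nms) + 1L,
                dimnames = list(NULL, c(nms, "median_os")))
  cover <- matrix(NA, replicates, length(nms), dimnames = list(NULL, nms))
  for (r in seq_len(replicates)) {
    pool <- generate_study_pool(cfg, seed = NULL)
    for (nm in nms) {
      p <- pool_proportions(pool[[paste0("events_", nm)]], pool$n)
      est[r, nm] <- p$point
      cover[r, nm] <- p$ci_low <= cfg$true_props[[nm]] &&
        cfg$true_props[[nm]] <= p$ci_high
    }
    est[r, "median_os"] <- pooled_median(pool$median_os, pool$n)$m_p
  }
  truth <- c(cfg$true_props, median_os = cfg$true_median)
  data.frame(parameter = colnames(est),
             truth = unname(truth),
             mean_estimate = colMeans(est),
             bias = colMeans(est) - unname(truth),
             coverage = c(colMeans(cover), NA_real_),
             row.names = NULL)
}
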