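#' @title Meta-analytic synthesis of trial-level inputs
#' @name meta_pooling
#' @description
#' Transition probabilities are synthesised from per-study event counts by
#' Freeman-Tukey double-arcsine transformation followed by DerSimonian-Laird
#' random-effects pooling, with Miller's back-transformation to the
#' probability scale. Median overall survival is pooled on the hazard scale
#' under an exponential survival assumption: each study median is converted
#' to its constant hazard, hazards are averaged with sample-size weights,
#' and the pooled hazard is converted back to a median -- algebraically a
#' weighted harmonic mean of the study medians.
NULL

#' Freeman-Tukey double-arcsine transformation
#'
#' Variance-stabilising transform for a binomial proportion:
#' `t = (asin(sqrt(r/(n+1))) + asin(sqrt((r+1)/(n+1)))) / 2` with
#' within-study variance `1/(4n+2)`. Unlike the raw proportion, `t` has a
#' variance that does not depend on the unknown proportion, which makes
#' inverse-variance pooling well behaved at 0% and 100% event rates.
#'
#' @param r Event count(s), `0 <= r <= n`.
#' @param n Sample size(s), `n >= 1`.
#' @return A `data.frame` with columns `r`, `n`, `t` (radians) and `var_t`.
#' @export
ft_transform <- function(r, n) {
  if (length(r) != length(n)) stop("r and n must have equal length")
  if (any(n < 1)) stop("n must be at least 1")
  if (any(r < 0) || any(r > n)) stop("event counts must satisfy 0 <= r <= n")
  t <- (asin(sqrt(r / (n + 1))) + asin(sqrt((r + 1) / (n + 1)))) / 2
  data.frame(r = r, n = n, t = t, var_t = 1 / (4 * n + 2))
}

#' Back-transform a pooled double-arcsine value to a proportion
#'
#' Miller's inversion of the double-arcsine transform, using a mean sample
#' size (conventionally the harmonic mean across studies) for the
#' correction term. Results are clamped to \[0, 1\]; values of `t` at or
#' beyond the transform's boundaries map to 0 or 1.
#'
#' @param t Pooled transformed value(s), radians.
#' @param n_mean Mean sample size used in the correction (harmonic mean
#'   recommended).
#' @return Proportion(s) in \[0, 1\].
#' @export
ft_inverse <- function(t, n_mean) {
  if (n_mean <= 0) stop("n_mean must be positive")
  # attainable bounds of the transform at this sample size: t below the
  # all-failures value maps to 0, above the all-successes value to 1
  t_min <- asin(sqrt(1 / (n_mean + 1))) / 2
  t_max <- (asin(sqrt(n_mean / (n_mean + 1))) + pi / 2) / 2
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= t_min) { out[i] <- 0; next }
    if (ti >= t_max) { out[i] <- 1; next }
    s2 <- sin(2 * ti)
    inner <- s2 + (s2 - 1 / s2) / n_mean
    val <- 0.5 * (1 - sign(cos(2 * ti)) * sqrt(pmax(0, 1 - inner^2)))
    out[i] <- min(max(val, 0), 1)
  }
  out
}

#' Random-effects pooling of transformed proportions
#'
#' DerSimonian-Laird pooling on the double-arcsine scale: the heterogeneity
#' variance `tau^2` is estimated from Cochran's Q (floored at zero), study
#' weights are `1/(var_t + tau^2)`, and the pooled value and its 95% CI are
#' back-transformed with [ft_inverse()] using the harmonic mean of the study
#' sizes. A single study is returned as-is with a warning.
#'
#' @param ts A `data.frame` from [ft_transform()] (columns `t`, `var_t`, `n`).
#' @return A [proportion_estimate()] with attributes `tau2`, `k`, `t_pooled`
#'   and `se_t`.
#' @export
pool_random_effects <- function(ts) {
  stopifnot(is.data.frame(ts), all(c("t", "var_t", "n") %in% names(ts)))
  k <- nrow(ts)
  if (k < 1L) stop("need at least one study")
  n_harm <- k / sum(1 / ts$n)
  if (k == 1L) {
    warning("single study: returning its own estimate; no heterogeneity ",
            "can be estimated")
    se <- sqrt(ts$var_t)
    est <- proportion_estimate(
      point = ft_inverse(ts$t, n_harm),
      ci = c(ft_inverse(ts$t - 1.96 * se, n_harm),
             ft_inverse(ts$t + 1.96 * se, n_harm)))
    attr(est, "tau2") <- 0; attr(est, "k") <- 1L
    attr(est, "t_pooled") <- ts$t; attr(est, "se_t") <- se
    return(est)
  }
  w <- 1 / ts$var_t
  t_fixed <- sum(w * ts$t) / sum(w)
  Q <- sum(w * (ts$t - t_fixed)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  w_star <- 1 / (ts$var_t + tau2)
  t_pooled <- sum(w_star * ts$t) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  est <- proportion_estimate(
    point = ft_inverse(t_pooled, n_harm),
    ci = c(ft_inverse(t_pooled - 1.96 * se, n_harm),
           ft_inverse(t_pooled + 1.96 * se, n_harm)),
    sd = ft_inverse(t_pooled + se, n_harm) - ft_inverse(t_pooled, n_harm))
  attr(est, "tau2") <- tau2; attr(est, "k") <- k
  attr(est, "t_pooled") <- t_pooled; attr(est, "se_t") <- se
  est
}

#' Pool proportions from raw counts
#'
#' Convenience wrapper: [ft_transform()] then [pool_random_effects()].
#'
#' @param r Event counts.
#' @param n Sample sizes.
#' @return See [pool_random_effects()].
#' @export
pool_proportions <- function(r, n) pool_random_effects(ft_transform(r, n))

#' Pooled median survival under exponential hazards
#'
#' Each study median `m_i` implies a constant hazard `lambda_i = ln 2 / m_i`.
#' Hazards are pooled with sample-size weights `w_i = n_i / sum(n)` and the
#' pooled hazard converted back: `m_p = ln 2 / sum(w_i lambda_i)`, i.e. the
#' weighted harmonic mean of the medians. Averaging on the hazard scale
#' avoids the upward bias of arithmetically averaging medians.
#'
#' @param m Study median survivals, months (> 0).
#' @param n Study sample sizes (>= 1).
#' @return An object of class `pooled_median`: list with `m_p` (months),
#'   `weights` (summing to 1), `lambdas` (per-study hazards, 1/month) and
#'   `lambda_p`.
#' @export
pooled_median <- function(m, n) {
  if (length(m) != length(n)) stop("m and n must have equal length")
  if (length(m) < 1L) stop("need at least one study")
  if (any(!is.finite(m)) || any(m <= 0)) stop("all medians must be positive and finite")
  if (any(n < 1)) stop("all sample sizes must be at least 1")
  w <- n / sum(n)
  lam <- log(2) / m
  lam_p <- sum(w * lam)
  structure(list(m_p = log(2) / lam_p, weights = w,
                 lambdas = lam, lambda_p = lam_p),
            class = "pooled_median")
}

#' @export
print.pooled_median <- function(x, ...) {
  cat(sprintf("pooled median %.3f months (pooled hazard %.5f /month, k = %d)\n",
              x$m_p, x$lambda_p, length(x$weights)))
  invisible(x)
}

#' Pool every outcome in a study-record table
#'
#' Runs [pool_proportions()] for each `events_<outcome>` column (rows with a
#' missing count are dropped per outcome) and [pooled_median()] on
#' `median_os`, separately per pathway.
#'
#' @param records A `study_records` data frame from [load_study_records()].
#' @return A `data.frame` with one row per (pathway, outcome): point, CI,
#'   `tau2`, `k_studies`; pooled medians appear as outcome `median_os`.
#' @export
pool_study_records <- function(records) {
  out <- list()
  for (pw in unique(records$pathway)) {
    sub <- records[records$pathway == pw, , drop = FALSE]
    for (col in grep("^events_", names(sub), value = TRUE)) {
      keep <- !is.na(sub[[col]])
      if (!any(keep)) next
      est <- pool_proportions(sub[[col]][keep], sub$n[keep])
      out[[length(out) + 1L]] <- data.frame(
        pathway = pw, outcome = sub("^events_", "", col),
        point = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
        tau2 = attr(est, "tau2"), k_studies = attr(est, "k"))
    }
    if ("median_os" %in% names(sub)) {
      keep <- !is.na(sub$median_os)
      if (any(keep)) {
        pm <- pooled_median(sub$median_os[keep], sub$n[keep])
        out[[length(out) + 1L]] <- data.frame(
          pathway = pw, outcome = "median_os",
          point = pm$m_p, ci_low = NA_real_, ci_high = NA_real_,
          tau2 = NA_real_, k_studies = sum(keep))
      }
    }
  }
  do.call(rbind, out)
}
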