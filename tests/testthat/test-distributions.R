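# the fitted uncertainty distributions published for the model's parameters
table2_specs <- function() {
  cfg <- baseline_config()
  specs <- lapply(c(cfg$params$nat, cfg$params$sf), `[[`, "distribution")
  specs[!vapply(specs, is.null, logical(1))]
}

test_that("quantile functions honour their closed forms and supports", {
  # Cauchy median equals its location parameter
  cauchy <- distribution_spec("cauchy", c(sigma = 0.00373, mu = 0.00639))
  expect_equal(dist_quantile(cauchy, 0.5), 0.00639, tolerance = 1e-12)
  # GEV at u = exp(-1) returns mu for any shape/scale
  for (k in c(-0.5, -1e-13, 0.3, 0.45856))
    expect_equal(
      dist_quantile(distribution_spec("gev", c(k = k, sigma = 0.011, mu = 0.009)),
                    exp(-1)),
      0.009, tolerance = 1e-10)
  # Johnson SB quantiles stay inside (xi, xi + lambda)
  jsb <- distribution_spec("johnson_sb",
                           c(gamma = 1.7195, delta = 1.0417,
                             lambda = 0.04849, xi = -0.00113))
  qs <- dist_quantile(jsb, c(1e-6, 0.01, 0.5, 0.99, 1 - 1e-6))
  expect_true(all(qs > -0.00113 & qs < -0.00113 + 0.04849))
  expect_error(dist_quantile(cauchy, c(0.2, 1)), "strictly inside")
})

test_that("CDF and quantile are exact inverses for every fitted family", {
  u <- c(1e-6, 0.001, 0.025, 0.2, 0.5, 0.8, 0.975, 0.999, 1 - 1e-6)
  specs <- table2_specs()
  expect_length(specs, 12L)  # every parameter carries a fitted distribution
  fams <- unique(vapply(specs, `[[`, "", "family"))
  expect_setequal(fams, c("gev", "gpd", "johnson_sb", "burr", "pearson5",
                          "log_pearson3", "cauchy", "pareto2"))
  for (spec in specs)
    expect_equal(dist_cdf(spec, dist_quantile(spec, u)), u, tolerance = 1e-8)
  # and for the standard extensions
  std <- list(distribution_spec("normal", c(mean = 0.4, sd = 0.1)),
              distribution_spec("lognormal", c(meanlog = -1, sdlog = 0.5)),
              distribution_spec("beta", c(shape1 = 3, shape2 = 5)),
              distribution_spec("gamma", c(shape = 2, rate = 4)),
              distribution_spec("weibull", c(shape = 1.5, scale = 2)),
              distribution_spec("exponential", c(rate = 0.3)))
  for (spec in std)
    expect_equal(dist_cdf(spec, dist_quantile(spec, u)), u, tolerance = 1e-8)
})

test_that("spec construction validates family and parameters", {
  expect_error(distribution_spec("nosuch", c(a = 1)), "unknown distribution")
  expect_error(distribution_spec("gev", c(k = 0.1, mu = 0)), "requires parameter")
  expect_error(distribution_spec("gev", c(k = 0.1, sigma = -1, mu = 0)),
               "strictly positive")
  # published table spellings are accepted
  expect_equal(canonical_family("Generalized Extreme Value"), "gev")
  expect_equal(canonical_family("Pareto 2"), "pareto2")
  expect_equal(canonical_family("Log-Pearson 3"), "log_pearson3")
})

test_that("maximum-likelihood fitting recovers known parameters", {
  set.seed(42)
  x <- dist_sample(distribution_spec("cauchy", c(sigma = 0.1, mu = 0.5)), 5000)
  fit <- fit_mle(x, "cauchy")
  expect_true(attr(fit, "converged"))
  expect_lt(abs(fit$params[["mu"]] - 0.5), 0.02)
  expect_lt(abs(fit$params[["sigma"]] - 0.1), 0.02)

  x <- dist_sample(distribution_spec("gev", c(k = 0.2, sigma = 1, mu = 3)), 5000)
  fit <- fit_mle(x, "gev")
  expect_true(attr(fit, "converged"))
  expect_equal(unname(fit$params["k"]), 0.2, tolerance = 0.05)
  expect_equal(unname(fit$params["sigma"]), 1, tolerance = 0.05)

  expect_error(fit_mle(rep(0.3, 50), "normal"), "constant")
  expect_error(fit_mle(c(0.1, 0.2), "normal"), "at least 5")
})

test_that("fitted gamma parameters agree with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(9)
  x <- rgamma(2000, shape = 2.5, rate = 1.7)
  ours <- fit_mle(x, "gamma")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(unname(ours$params["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(unname(ours$params["rate"]), unname(ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("Anderson-Darling statistic behaves as a goodness-of-fit measure", {
  set.seed(7)
  spec <- distribution_spec("normal", c(mean = 2, sd = 0.5))
  x <- dist_sample(spec, 2000)
  a_self <- anderson_darling(x, spec)
  expect_lt(a_self, 2)  # data drawn from the spec itself fits well
  shifted <- distribution_spec("normal", c(mean = 3, sd = 0.5))
  expect_gt(anderson_darling(x, shifted), a_self)
  # defined and finite for a single observation
  expect_true(is.finite(anderson_darling(0.5, spec)))
  # boundary CDF values are clamped with a warning, not an error
  tight <- distribution_spec("beta", c(shape1 = 200, shape2 = 200))
  expect_warning(a <- anderson_darling(c(1e-9, 0.5, 1 - 1e-9), tight), "clamping")
  expect_true(is.finite(a))
})

test_that("model selection picks the best Anderson-Darling fit", {
  set.seed(21)
  x <- rexp(1500, rate = 2)
  best <- select_best_fit(x, c("cauchy", "gev", "pareto2", "exponential"))
  expect_false(best$family == "cauchy")
  expect_true(is.finite(best$ad_stat))
  fits <- attr(best, "fits")
  expect_equal(best$ad_stat, min(fits$ad_stat))
  # a single surviving candidate is returned regardless of its statistic:
  # beta cannot fit data outside (0, 1), normal remains
  y <- rnorm(200, 10, 2)
  best2 <- select_best_fit(y, c("beta", "normal"))
  expect_equal(best2$family, "normal")
  expect_error(select_best_fit(x, "gev"), "at least two")
})
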