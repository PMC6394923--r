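test_that("Freeman-Tukey transform matches its defining formula", {
  # r = 0, n = 1: t = (asin(0) + asin(sqrt(1/2))) / 2 = pi/8
  ts <- ft_transform(0, 1)
  expect_equal(ts$t, pi / 8, tolerance = 1e-12)
  expect_equal(ts$var_t, 1 / 6)
  # direct numeric evaluation at r = 5, n = 10
  ts <- ft_transform(5, 10)
  expect_equal(ts$t, (asin(sqrt(5 / 11)) + asin(sqrt(6 / 11))) / 2,
               tolerance = 1e-12)
  expect_equal(ts$var_t, 1 / 42)
  # symmetry: t(0, n) + t(n, n) = pi/2
  for (n in c(1, 7, 50, 200))
    expect_equal(ft_transform(0, n)$t + ft_transform(n, n)$t, pi / 2,
                 tolerance = 1e-12)
  expect_error(ft_transform(5, 4), "r <= n")
  expect_error(ft_transform(1, 0), "at least 1")
})

test_that("back-transformation inverts the transform", {
  # symmetry point of the double arcsine maps near 0.5
  expect_equal(ft_inverse(pi / 4, 50), 0.5, tolerance = 0.02)
  # round trip at large n recovers r/n within 1/n
  for (r in c(3, 25, 60, 97)) {
    n <- 100
    expect_equal(ft_inverse(ft_transform(r, n)$t, n), r / n, tolerance = 1 / n)
  }
  # boundaries clamp
  expect_equal(ft_inverse(0, 100), 0)
  expect_equal(ft_inverse(pi / 2, 100), 1)
})

test_that("DerSimonian-Laird pooling matches a hand-coded two-study oracle", {
  # independent step-by-step computation for (r, n) = (30, 100), (60, 100)
  t1 <- (asin(sqrt(30 / 101)) + asin(sqrt(31 / 101))) / 2
  t2 <- (asin(sqrt(60 / 101)) + asin(sqrt(61 / 101))) / 2
  v <- 1 / 402
  w <- 1 / v
  t_fixed <- (t1 + t2) / 2
  Q <- w * ((t1 - t_fixed)^2 + (t2 - t_fixed)^2)
  c_dl <- 2 * w - 2 * w^2 / (2 * w)
  tau2 <- max(0, (Q - 1) / c_dl)
  w_star <- 1 / (v + tau2)
  t_pool <- (w_star * t1 + w_star * t2) / (2 * w_star)
  se <- sqrt(1 / (2 * w_star))

  est <- pool_proportions(c(30, 60), c(100, 100))
  expect_equal(attr(est, "t_pooled"), t_pool, tolerance = 1e-12)
  expect_equal(attr(est, "tau2"), tau2, tolerance = 1e-12)
  expect_equal(attr(est, "se_t"), se, tolerance = 1e-12)
  expect_equal(est$point, ft_inverse(t_pool, 100), tolerance = 1e-12)
})

test_that("pooling agrees with metafor's PFT + DL implementation", {
  skip_if_not_installed("metafor")
  r <- c(4, 12, 30, 7, 19); n <- c(25, 40, 95, 33, 60)
  ours <- pool_proportions(r, n)
  es <- metafor::escalc(measure = "PFT", xi = r, ni = n)
  fit <- metafor::rma(yi = es$yi, vi = es$vi, method = "DL")
  expect_equal(attr(ours, "t_pooled"), as.numeric(fit$b), tolerance = 1e-8)
  expect_equal(attr(ours, "tau2"), fit$tau2, tolerance = 1e-8)
})

test_that("homogeneous pools collapse to the common proportion", {
  est <- pool_proportions(rep(30, 6), rep(100, 6))
  expect_equal(attr(est, "tau2"), 0)
  expect_equal(est$point, 0.3, tolerance = 0.01)
  # pooled point always within the observed range of proportions
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:200, 5)
    r <- rbinom(5, n, runif(1, 0.1, 0.9))
    est <- pool_proportions(r, n)
    expect_gte(est$point, min(r / n) - 1e-6)
    expect_lte(est$point, max(r / n) + 1e-6)
  }
})

test_that("pooling is invariant to ordering and to duplicating a study", {
  r <- c(10, 35, 52); n <- c(40, 80, 120)
  a <- pool_proportions(r, n)
  b <- pool_proportions(rev(r), rev(n))
  expect_equal(a$point, b$point, tolerance = 1e-12)
  expect_equal(attr(a, "tau2"), attr(b, "tau2"), tolerance = 1e-12)
  # one study duplicated k times pools to that study's own value
  suppressWarnings(single <- pool_proportions(30, 100))
  dup <- pool_proportions(rep(30, 4), rep(100, 4))
  expect_equal(dup$point, single$point, tolerance = 1e-6)
})

test_that("a single study is returned as-is with a warning", {
  expect_warning(est <- pool_proportions(30, 100), "single study")
  expect_equal(est$point, ft_inverse(ft_transform(30, 100)$t, 100))
})

test_that("pooled median is the weighted harmonic mean of study medians", {
  # worked two-study case: w = (2/3, 1/3), m_p = 1/(2/3/12 + 1/3/24) = 14.4
  pm <- pooled_median(c(12, 24), c(100, 50))
  expect_equal(pm$m_p, 14.4, tolerance = 1e-12)
  expect_equal(pm$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(pm$weights), 1, tolerance = 1e-9)
  expect_equal(pm$lambdas, log(2) / c(12, 24))
  # identity cases
  expect_equal(pooled_median(17.4, 30)$m_p, 17.4)
  expect_equal(pooled_median(rep(20, 5), c(10, 20, 30, 40, 50))$m_p, 20)
  expect_error(pooled_median(c(12, -1), c(10, 10)), "positive")
})

test_that("harmonic pooling never exceeds the arithmetic weighted mean", {
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    m <- runif(k, 5, 40); n <- sample(10:300, k)
    pm <- pooled_median(m, n)
    expect_lte(pm$m_p, sum(pm$weights * m) + 1e-12)
    expect_gte(pm$m_p, min(m) - 1e-12)
    expect_lte(pm$m_p, max(m) + 1e-12)
  }
  # equality iff all medians equal
  expect_equal(pooled_median(rep(13, 3), c(5, 6, 7))$m_p, 13)
})
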