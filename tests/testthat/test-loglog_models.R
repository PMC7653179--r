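# Log-log model family: fits, estimators, tests

test_that("an exact line is recovered exactly", {
  atm <- line_atm(gamma = -1, intercept = 2)
  fit <- fit_loglog_linear(atm)
  expect_equal(fit$gamma, -1)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r2, 1)
  expect_lt(fit$rss, 1e-20)
})

test_that("the linear fit matches the normal equations and covers the truth", {
  atm <- line_atm(gamma = -1, sigma = 0.05, seed = 101)
  fit <- fit_loglog_linear(atm)

  # independent oracle: closed-form normal equations
  X <- cbind(1, log(atm$x))
  y <- log(atm$rate)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1L], tolerance = 1e-12)
  expect_equal(fit$gamma, beta[2L], tolerance = 1e-12)
  r <- y - X %*% beta
  expect_equal(fit$rss, sum(r^2), tolerance = 1e-12)
  s2 <- sum(r^2) / (fit$n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2L, 2L])
  expect_equal(fit$se_gamma, se, tolerance = 1e-12)

  expect_true(fit$ci_gamma[1L] <= -1 && -1 <= fit$ci_gamma[2L])
  expect_lte(fit$r2_adjusted, fit$r2)
  expect_error(fit_loglog_linear(line_atm(x = c(1, 2))), "at least 3")
})

test_that("the quadratic linearity test behaves at both extremes", {
  # exact line: the quadratic term cannot improve a perfect fit
  t_line <- test_linearity_quadratic(line_atm(gamma = -1))
  expect_equal(t_line$p_value, 1)
  expect_equal(t_line$statistic, 0)

  # strong curvature: ln mu = -(ln x)^2
  x <- who9$midpoint
  atm_curved <- as_atm(data.frame(x = x, rate = exp(-log(x)^2)))
  t_curved <- test_linearity_quadratic(atm_curved)
  expect_lt(t_curved$p_value, 0.05)
  expect_true(t_curved$rejected)

  # noisy but linear data: t-test and F-test agree
  atm_noisy <- line_atm(gamma = -1, sigma = 0.1, seed = 5)
  tn <- test_linearity_quadratic(atm_noisy)
  expect_equal(tn$p_value, tn$f_p_value, tolerance = 1e-12)
  expect_equal(tn$statistic^2, tn$f_statistic, tolerance = 1e-10)
})

test_that("the quadratic test holds its level under a true line", {
  set.seed(7)
  n_rep <- 1000L
  rej <- 0L
  for (i in seq_len(n_rep)) {
    atm <- line_atm(gamma = -1, sigma = 0.05)
    if (test_linearity_quadratic(atm)$rejected) rej <- rej + 1L
  }
  rate <- rej / n_rep
  se3 <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_close(rate, 0.05, se3)
})

test_that("the one-parameter estimator has its closed form and R2", {
  atm <- as_atm(data.frame(x = c(1, 2), rate = c(2, 1)))
  fit <- fit_inverse_proportion(atm)
  expect_equal(fit$mu1, 2)
  expect_equal(fit$r2_b, 1)

  # degenerate: equal rates have zero total variance
  flat <- as_atm(data.frame(x = c(1, 2), rate = c(1, 1)))
  ffit <- fit_inverse_proportion(flat)
  expect_equal(ffit$mu1, sqrt(2))
  expect_false(ffit$r2_b_defined)
  expect_true(is.na(ffit$r2_b))
})

test_that("the closed-form scale estimator is the least-squares minimizer", {
  for (seed in 1:5) {
    atm <- line_atm(gamma = -1, sigma = 0.2, seed = seed)
    fit <- fit_inverse_proportion(atm)
    # independent oracle: numeric minimization of the RSS in ln(mu1)
    rss <- function(ln_mu1) {
      sum((log(atm$rate) - (ln_mu1 - log(atm$x)))^2)
    }
    opt <- optimize(rss, fit$ln_mu1 + c(-2, 2), tol = 1e-12)
    expect_close(fit$ln_mu1, opt$minimum, 1e-6)
    expect_close(fit$rss, opt$objective, 1e-9)
  }
})

test_that("fixed-slope t-tests reject and retain correctly", {
  # OLS slope exactly -1 with residual noise: statistic 0, p = 1
  atm <- line_atm_exact_slope(gamma = -1)
  fit <- fit_loglog_linear(atm)
  expect_equal(fit$gamma, -1, tolerance = 1e-12)
  tt <- test_fixed_slope(fit, -1)
  expect_equal(tt$statistic, 0, tolerance = 1e-8)
  expect_equal(tt$p_value, 1, tolerance = 1e-8)

  # steep decline against age-independence
  steep <- fit_loglog_linear(line_atm(gamma = -1.5, sigma = 0.02, seed = 3))
  expect_lt(test_fixed_slope(steep, 0)$p_value, 0.05)

  # perfect fit: the test is degenerate
  exact <- fit_loglog_linear(line_atm(gamma = -1))
  expect_error(test_fixed_slope(exact, -1), "degenerate")
})

test_that("simulated reciprocal-frailty cohorts retain the slope -1 null", {
  spec0 <- scenario_preset("inverse_proportion", n_individuals = 1e5)
  retained <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    spec <- cohort_spec(1e5, spec0$dist, seed = i)
    rec <- simulate_cohort(spec, who9)
    atm <- build_atm(halley_aggregate(rec), c(0, 10))
    if (!is_complete(atm)) next
    fit <- fit_loglog_linear(atm)
    if (!test_fixed_slope(fit, -1)$rejected) retained <- retained + 1L
  }
  expect_gte(retained / n_rep, 0.9)
})

test_that("the nested F-test separates the models it should", {
  # slope exactly -1 with orthogonal noise: the extra parameter buys nothing
  atm <- line_atm_exact_slope(gamma = -1)
  lin <- fit_loglog_linear(atm)
  inv <- fit_inverse_proportion(atm)
  expect_gte(inv$rss, lin$rss - 1e-12)
  ft <- nested_f_test(lin, inv)
  expect_lt(ft$statistic, 1e-10)
  expect_gt(ft$p_value, 0.999)

  # the true slope is -0.7: inverse proportion is rejected
  atm2 <- line_atm(gamma = -0.7, sigma = 0.02, seed = 11)
  ft2 <- nested_f_test(fit_loglog_linear(atm2), fit_inverse_proportion(atm2))
  expect_lt(ft2$p_value, 0.05)

  # a perfect two-parameter fit cannot reject: p = 1 convention
  atm3 <- line_atm(gamma = -0.9)
  ft3 <- nested_f_test(fit_loglog_linear(atm3), fit_inverse_proportion(atm3))
  expect_equal(ft3$p_value, 1)

  # mismatched point sets are refused
  atm4 <- line_atm(gamma = -1, sigma = 0.05, seed = 12)
  expect_error(nested_f_test(fit_loglog_linear(atm2),
                             fit_inverse_proportion(atm4)),
               "identical points")
})

test_that("unadjusted R2 of the two-parameter model dominates Rb2", {
  gammas <- seq(-1.3, -0.7, length.out = 10)
  for (seed in 1:10) {
    atm <- line_atm(gamma = gammas[seed], sigma = 0.1, seed = seed)
    lin <- fit_loglog_linear(atm)
    inv <- fit_inverse_proportion(atm)
    expect_gte(lin$r2, inv$r2_b)
  }
})

test_that("residual diagnostics flag age signal and U-shapes", {
  # residuals identically zero
  exact <- fit_inverse_proportion(line_atm(gamma = -1))
  expect_equal(residual_independence_test(exact)$p_value, 1)

  # inverse-proportion fit on slope -0.7 data leaves a residual trend
  atm <- line_atm(gamma = -0.7, sigma = 0.02, seed = 13)
  inv <- fit_inverse_proportion(atm)
  rt <- residual_independence_test(inv)
  expect_lt(rt$p_value, 0.05)
  expect_match(rt$method, "slope of residuals")

  # U-shaped residuals around a linear fit
  x <- who9$midpoint
  lnx <- log(x)
  lnmu <- 2 - lnx + 0.2 * (lnx - mean(lnx))^2
  atm_u <- as_atm(data.frame(x = x, rate = exp(lnmu)))
  lin <- fit_loglog_linear(atm_u)
  ut <- residual_independence_test(lin)
  expect_lt(ut$p_value, 0.05)
  expect_match(ut$method, "U-shape")
})

test_that("the inverse-proportion curve and fold decrease are analytic", {
  expect_equal(hazard_inverse_proportion(1, 2), 2)
  expect_equal(hazard_inverse_proportion(1 / 365, 5) /
                 hazard_inverse_proportion(10, 5), 3650)
  expect_error(hazard_inverse_proportion(0, 1), "positive")
})
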