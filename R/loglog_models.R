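# Log-log model family: linear, quadratic, inverse proportion ------------
#
# All fits are plain unweighted least squares of ln(rate) on ln(age),
# natural logarithms throughout.  The model family, from general to nested:
#   quadratic:          ln mu = c + gamma ln x + delta (ln x)^2
#   linear (2 par):     ln mu = c + gamma ln x
#   inverse proportion: ln mu = ln(mu1) - ln x        (gamma fixed at -1)
# The inverse-proportion scale has the closed-form estimator
#   ln(mu1) = mean(ln mu_i + ln x_i),
# the least-squares minimizer with residual degrees of freedom n - 1.

.new_test <- function(statistic, p_value, df, null_hypothesis, alpha,
                      method, ...) {
  structure(
    list(statistic = statistic, p_value = p_value, df = df,
         null_hypothesis = null_hypothesis, alpha = alpha,
         rejected = is.finite(p_value) && p_value < alpha,
         method = method, ...),
    class = "atm_test"
  )
}

#' @export
print.atm_test <- function(x, ...) {
  cat(sprintf("%s\n  H0: %s\n  statistic = %.4g, df = %s, p = %.4g (%s at alpha = %g)\n",
              x$method, x$null_hypothesis, x$statistic,
              paste(x$df, collapse = ", "), x$p_value,
              if (x$rejected) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Two-parameter linear fit on the log-log scale
#'
#' Ordinary unweighted least squares of `ln(rate)` on `ln(age)`.  The slope
#' `gamma` measures the speed of the mortality decrease with age; `gamma = -1`
#' is the inverse-proportion special case.
#'
#' @param atm A complete `"atm"` object (or data frame with columns `x`,
#'   `rate`); at least 3 points.
#' @param conf_level Confidence level for the slope interval.
#' @param drop_undefined Drop zero-death points instead of refusing the fit.
#' @return An object of class `"loglog_fit"` with elements `intercept`,
#'   `gamma`, `se_gamma`, `ci_gamma`, `r2`, `r2_adjusted`, `rss`, `ss_total`,
#'   `n` and the fitted `data`.
#' @export
fit_loglog_linear <- function(atm, conf_level = 0.95, drop_undefined = FALSE) {
  d <- .log_points(atm, drop_undefined)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 points for the linear fit", call. = FALSE)
  fit <- stats::lm(lnmu ~ lnx, data = d)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a summary.lm warning
  gamma <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2L)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1L]),
      gamma = gamma, se_gamma = se,
      ci_gamma = c(lower = gamma - tq * se, upper = gamma + tq * se),
      conf_level = conf_level,
      r2 = sm$r.squared, r2_adjusted = sm$adj.r.squared,
      rss = sum(stats::resid(fit)^2),
      ss_total = sum((d$lnmu - mean(d$lnmu))^2),
      n = n, data = d, model = "loglog_linear"
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log linear fit (n = %d)\n  gamma = %.3f (%d%% CI %.3f, %.3f), intercept = %.3f\n  R2 = %.4f, adjusted R2 = %.4f, RSS = %.4g\n",
    x$n, x$gamma, round(100 * x$conf_level), x$ci_gamma[1L], x$ci_gamma[2L],
    x$intercept, x$r2, x$r2_adjusted, x$rss))
  invisible(x)
}

#' Quadratic test of log-log linearity
#'
#' Fits the full quadratic model `ln mu = c + gamma ln x + delta (ln x)^2`
#' and tests the null hypothesis that the quadratic coefficient `delta` is
#' zero, i.e. that the trajectory is linear in the log-log scale.  The
#' equivalent F-test of the quadratic model against the linear submodel is
#' reported alongside (its p-value equals the t-test's).
#'
#' @inheritParams fit_loglog_linear
#' @param alpha Significance level.
#' @return An `"atm_test"` (t-test of `delta = 0`) with extra elements
#'   `delta`, `f_statistic`, `f_df`, `f_p_value`.
#' @export
test_linearity_quadratic <- function(atm, alpha = 0.05,
                                     drop_undefined = FALSE) {
  d <- .log_points(atm, drop_undefined)
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 points for the quadratic test",
                   call. = FALSE)
  quad <- stats::lm(lnmu ~ lnx + I(lnx^2), data = d)
  lin <- stats::lm(lnmu ~ lnx, data = d)
  sm <- suppressWarnings(summary(quad))$coefficients
  delta <- unname(stats::coef(quad)[3L])
  rss_q <- sum(stats::resid(quad)^2)
  rss_l <- sum(stats::resid(lin)^2)
  if (rss_l < 1e-12 * max(1, sum(d$lnmu^2)) || !is.finite(sm[3L, 4L])) {
    # degenerate: the linear submodel already fits exactly, so the quadratic
    # term cannot improve it; perfect fits cannot reject
    tstat <- 0; p_t <- 1; fstat <- 0; p_f <- 1
  } else {
    tstat <- sm[3L, 3L]; p_t <- sm[3L, 4L]
    fstat <- max(0, (rss_l - rss_q) / (rss_q / (n - 3L)))
    p_f <- stats::pf(fstat, 1L, n - 3L, lower.tail = FALSE)
  }
  .new_test(tstat, p_t, df = n - 3L,
            null_hypothesis = "delta = 0 (trajectory linear in log-log scale)",
            alpha = alpha, method = "quadratic-term linearity test",
            delta = delta, f_statistic = fstat, f_df = c(1L, n - 3L),
            f_p_value = p_f)
}

#' One-parameter inverse-proportion fit
#'
#' Fits `mu(x) = mu1 / x` by least squares on the log-log scale.  The single
#' scale parameter has the closed form `ln(mu1) = mean(ln mu_i + ln x_i)`,
#' with residual degrees of freedom `n - 1`, and the coefficient of
#' determination is computed against the fixed slope -1 line.
#'
#' @inheritParams fit_loglog_linear
#' @return An object of class `"invprop_fit"` with elements `ln_mu1`, `mu1`,
#'   `rss`, `ss_total`, `r2_b` (`NA` when all `ln mu` are equal, flagged by
#'   `r2_b_defined = FALSE`), `n` and `data`.
#' @export
fit_inverse_proportion <- function(atm, drop_undefined = FALSE) {
  d <- .log_points(atm, drop_undefined)
  n <- nrow(d)
  if (n < 1L) stop("need at least one point", call. = FALSE)
  ln_mu1 <- mean(d$lnmu + d$lnx)
  resid <- d$lnmu - (ln_mu1 - d$lnx)
  rss <- sum(resid^2)
  ss_total <- sum((d$lnmu - mean(d$lnmu))^2)
  r2_b_defined <- n >= 2L && ss_total > 0
  structure(
    list(
      ln_mu1 = ln_mu1, mu1 = exp(ln_mu1),
      rss = rss, ss_total = ss_total,
      r2_b = if (r2_b_defined) 1 - rss / ss_total else NA_real_,
      r2_b_defined = r2_b_defined,
      n = n, data = d, model = "inverse_proportion"
    ),
    class = "invprop_fit"
  )
}

#' @export
print.invprop_fit <- function(x, ...) {
  cat(sprintf(
    "Inverse-proportion fit mu(x) = mu1/x (n = %d)\n  mu1 = %.5g per person-year, Rb2 = %s, RSS = %.4g\n",
    x$n, x$mu1,
    if (x$r2_b_defined) sprintf("%.4f", x$r2_b) else "undefined (zero total variance)",
    x$rss))
  invisible(x)
}

#' The inverse-proportion hazard curve
#'
#' @param x Ages in years, positive.
#' @param mu1 Positive scale: the rate at age 1 year, per person-year.
#' @return `mu1 / x`, per person-year.
#' @export
hazard_inverse_proportion <- function(x, mu1) {
  if (any(x <= 0)) stop("age must be positive", call. = FALSE)
  if (mu1 <= 0) stop("mu1 must be positive", call. = FALSE)
  mu1 / x
}

#' t-test of a fixed log-log slope
#'
#' Two-sided t-test of `gamma = slope0` in the two-parameter linear model,
#' with `n - 2` degrees of freedom.  The slopes of interest are 0
#' (age-independence), -1 (inverse proportion) and -2 (the
#' uniform-frailty regime), but any value may be tested.
#'
#' @param fit A [fit_loglog_linear()] result.
#' @param slope0 Null-hypothesis slope.
#' @param alpha Significance level.
#' @return An `"atm_test"`.
#' @export
test_fixed_slope <- function(fit, slope0, alpha = 0.05) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (!is.finite(fit$se_gamma) || fit$se_gamma <= 0 ||
      fit$rss < 1e-12 * max(1, sum(fit$data$lnmu^2))) {
    stop("degenerate test: the linear fit is perfect (zero slope standard error)",
         call. = FALSE)
  }
  tstat <- (fit$gamma - slope0) / fit$se_gamma
  p <- 2 * stats::pt(-abs(tstat), df = fit$n - 2L)
  .new_test(tstat, p, df = fit$n - 2L,
            null_hypothesis = sprintf("gamma = %g", slope0), alpha = alpha,
            method = "fixed-slope t-test", slope0 = slope0)
}

#' Nested F-test: linear model vs inverse proportion
#'
#' Tests whether the two-parameter linear model fits significantly better
#' than the one-parameter inverse-proportion model nested within it:
#' `F = (RSS_1par - RSS_2par) / (RSS_2par / (n - 2))` on `(1, n - 2)` degrees
#' of freedom.  A zero two-parameter RSS (perfect linear fit) is handled with
#' the convention `p = 1`: perfect fits cannot reject.
#'
#' @param linear A [fit_loglog_linear()] result.
#' @param invprop A [fit_inverse_proportion()] result on the same points.
#' @param alpha Significance level.
#' @return An `"atm_test"`.
#' @export
nested_f_test <- function(linear, invprop, alpha = 0.05) {
  stopifnot(inherits(linear, "loglog_fit"), inherits(invprop, "invprop_fit"))
  if (linear$n != invprop$n ||
      max(abs(linear$data$lnx - invprop$data$lnx)) > 1e-12 ||
      max(abs(linear$data$lnmu - invprop$data$lnmu)) > 1e-12) {
    stop("the two fits were not produced on identical points", call. = FALSE)
  }
  n <- linear$n
  if (linear$rss <= .Machine$double.eps * max(1, invprop$rss)) {
    return(.new_test(0, 1, df = c(1L, n - 2L),
                     null_hypothesis = "inverse proportion suffices (gamma = -1)",
                     alpha = alpha, method = "nested F-test (2-par vs 1-par)"))
  }
  fstat <- max(0, (invprop$rss - linear$rss) / (linear$rss / (n - 2L)))
  p <- stats::pf(fstat, 1L, n - 2L, lower.tail = FALSE)
  .new_test(fstat, p, df = c(1L, n - 2L),
            null_hypothesis = "inverse proportion suffices (gamma = -1)",
            alpha = alpha, method = "nested F-test (2-par vs 1-par)")
}

#' Residual age-independence diagnostics
#'
#' Checks that fit residuals carry no age signal.  For the one-parameter
#' inverse-proportion fit this is a t-test of the slope of the residuals on
#' `ln(age)`; for the two-parameter linear fit (whose residuals are
#' orthogonal to `ln(age)` by construction) it is the quadratic-term t-test,
#' a proxy for U-shaped residuals.  Residuals that are identically zero give
#' `p = 1` by convention.
#'
#' @param fit A [fit_loglog_linear()] or [fit_inverse_proportion()] result.
#' @param alpha Significance level.
#' @return An `"atm_test"` whose `method` labels which diagnostic was run.
#' @export
residual_independence_test <- function(fit, alpha = 0.05) {
  d <- fit$data
  n <- nrow(d)
  if (inherits(fit, "invprop_fit")) {
    res <- d$lnmu - (fit$ln_mu1 - d$lnx)
    if (n < 3L) stop("need at least 3 points", call. = FALSE)
    method <- "residual age-independence (slope of residuals on ln age)"
    h0 <- "residual slope on ln(age) = 0"
    if (max(abs(res)) < 1e-12) return(.new_test(0, 1, n - 2L, h0, alpha, method))
    rfit <- suppressWarnings(summary(stats::lm(res ~ d$lnx)))$coefficients
    return(.new_test(rfit[2L, 3L], rfit[2L, 4L], n - 2L, h0, alpha, method))
  }
  if (inherits(fit, "loglog_fit")) {
    res <- d$lnmu - (fit$intercept + fit$gamma * d$lnx)
    if (n < 4L) stop("need at least 4 points", call. = FALSE)
    method <- "residual U-shape proxy (quadratic term in ln age)"
    h0 <- "residual quadratic coefficient in ln(age) = 0"
    if (max(abs(res)) < 1e-12) return(.new_test(0, 1, n - 3L, h0, alpha, method))
    rfit <- suppressWarnings(summary(stats::lm(res ~ d$lnx + I(d$lnx^2))))$coefficients
    return(.new_test(rfit[3L, 3L], rfit[3L, 4L], n - 3L, h0, alpha, method))
  }
  stop("fit must be a 'loglog_fit' or 'invprop_fit'", call. = FALSE)
}
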