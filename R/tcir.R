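# Congenital individual risks: frailty densities and induced hazards ------
#
# Each newborn carries a fixed congenital risk r (per person-year); the
# subpopulation at level r survives as S(r, x) = exp(-r x).  The observed
# population-level death intensity at age x, relative to the initial
# population (whose size stays nearly constant because the large majority is
# unimpaired or nearly so), is
#
#   mu(x) = integral f(r) r exp(-r x) dr
#
# over the risk density f.  The shape of f sets the log-log slope of the
# trajectory: a density proportional to 1/r gives mu(x) ~ mu1/x (slope -1); a
# flat density gives mu(x) ~ x^-2 (slope -2); a 1/r density truncated at
# r_max gives the bending curve mu(x) = (mu1/x)(1 - exp(-r_max x)), flat
# (about mu1 r_max) while r_max x < 1 and inverse-proportional later.

.new_frailty <- function(family, kind, r = NULL, r_min = NULL, r_max = NULL,
                         mass = 1, c = NULL) {
  structure(
    list(family = family, kind = kind, r = r, r_min = r_min, r_max = r_max,
         mass = mass, c = c),
    class = "frailty_dist"
  )
}

#' Frailty distributions over congenital risk
#'
#' Constructors for the supported families of the congenital-risk density
#' `f(r)` (risk `r` in deaths per person-year):
#'
#' * `frailty_point_mass(r)`: every impaired individual has the same risk.
#' * `frailty_reciprocal(r_min, r_max)`: density proportional to `1/r` on
#'   `(r_min, r_max]` ("the more severe the impairment, the rarer it is");
#'   induces the inverse-proportion trajectory, bending below age
#'   `1/r_max`.
#' * `frailty_uniform(r_max)`: flat density on `(0, r_max]` (no selection
#'   against severe impairments); induces the slope -2 regime.
#' * `frailty_mixture(impaired, p_impaired)`: fraction `p_impaired` follows
#'   the `impaired` family, the remainder is unimpaired (`r = 0`).
#'
#' `mass` is the probability carried by the impaired component (the density
#' integrates to `mass`).  For the interval families the density scale `c`
#' may be given instead of `mass` (then `mass = c log(r_max/r_min)` resp.
#' `c r_max`), which is convenient for theory curves where `c` plays the role
#' of the hazard scale `mu1`.
#'
#' @param r,r_min,r_max Risk levels per person-year; `r_min >= 0` (strictly
#'   positive for the reciprocal family), `r_max > r_min`.
#' @param mass Probability mass of the impaired component, in `[0, 1]` for
#'   sampling (larger values are allowed for theory curves).
#' @param c Density scale constant, alternative to `mass`.
#' @param impaired A `frailty_dist` with `mass = 1` describing the impaired
#'   sub-family.
#' @param p_impaired Impaired fraction in `[0, 1]`.
#' @return An object of class `"frailty_dist"`.
#' @name frailty_distributions
NULL

#' @rdname frailty_distributions
#' @export
frailty_point_mass <- function(r, mass = 1) {
  stopifnot(r >= 0, mass >= 0)
  .new_frailty("point_mass", "point_mass", r = r, mass = mass)
}

#' @rdname frailty_distributions
#' @export
frailty_reciprocal <- function(r_min, r_max, mass = 1, c = NULL) {
  stopifnot(r_min > 0, r_max > r_min)
  if (!is.null(c)) mass <- c * log(r_max / r_min)
  else c <- mass / log(r_max / r_min)
  .new_frailty("reciprocal", "reciprocal", r_min = r_min, r_max = r_max,
               mass = mass, c = c)
}

#' @rdname frailty_distributions
#' @export
frailty_uniform <- function(r_max, mass = 1, c = NULL) {
  stopifnot(r_max > 0)
  if (!is.null(c)) mass <- c * r_max else c <- mass / r_max
  .new_frailty("uniform", "uniform", r_min = 0, r_max = r_max,
               mass = mass, c = c)
}

#' @rdname frailty_distributions
#' @export
frailty_mixture <- function(impaired, p_impaired) {
  stopifnot(inherits(impaired, "frailty_dist"),
            p_impaired >= 0, p_impaired <= 1)
  if (abs(impaired$mass - 1) > 1e-12) {
    stop("the impaired sub-family must have mass 1", call. = FALSE)
  }
  out <- impaired
  out$family <- "mixture_with_unimpaired"
  out$mass <- p_impaired
  if (!is.null(out$c)) out$c <- out$c * p_impaired
  out
}

#' @export
print.frailty_dist <- function(x, ...) {
  par <- switch(x$kind,
    point_mass = sprintf("r = %g", x$r),
    reciprocal = sprintf("density c/r on (%g, %g], c = %g", x$r_min, x$r_max, x$c),
    uniform = sprintf("density %g on (0, %g]", x$c, x$r_max)
  )
  cat(sprintf("Frailty distribution: %s (%s), impaired mass %g\n",
              x$family, par, x$mass))
  invisible(x)
}

#' Bending hazard of the truncated reciprocal frailty family
#'
#' The two-parameter bending trajectory
#' \deqn{\mu(x) = (\mu_1 / x) (1 - e^{-r_{max} x}),}
#' approximately the constant \eqn{\mu_1 r_{max}} while
#' \eqn{r_{max} x < 1} and the inverse proportion \eqn{\mu_1 / x} for large
#' \eqn{r_{max} x}.  Continuously extended to `x = 0` by
#' \eqn{\mu_1 r_{max}}.
#'
#' @param x Ages in years, non-negative.
#' @param mu1 Positive scale per person-year.
#' @param r_max Positive maximal congenital risk per person-year.
#' @return Rates per person-year.
#' @export
#' @examples
#' hazard_bending(1, 1, 2)      # 1 - exp(-2)
#' hazard_bending(0.001, 1, 2)  # ~ mu1 * r_max
#' hazard_bending(100, 1, 2)    # ~ mu1 / x
hazard_bending <- function(x, mu1, r_max) {
  if (any(x < 0)) stop("age must be non-negative", call. = FALSE)
  stopifnot(mu1 > 0, r_max > 0)
  out <- numeric(length(x))
  z <- x == 0
  out[z] <- mu1 * r_max
  out[!z] <- -mu1 * expm1(-r_max * x[!z]) / x[!z]
  out
}

#' Hazard induced by a frailty density
#'
#' The population-level death intensity
#' \eqn{\mu(x) = \int f(r) r e^{-r x} dr}, relative to the (nearly constant)
#' initial population.  Closed forms are used for the point-mass, reciprocal
#' and uniform families; `method = "quadrature"` forces adaptive quadrature
#' instead (useful as an independent numerical check).
#'
#' Reciprocal family: \eqn{c (e^{-r_{min} x} - e^{-r_{max} x}) / x}, the
#' bending curve with \eqn{\mu_1 = c} when \eqn{r_{min} x} is negligible;
#' for \eqn{r_{max} \to \infty} it approaches \eqn{c / x} (slope -1).
#' Uniform family:
#' \eqn{c (1 - e^{-r_{max} x}(1 + r_{max} x)) / x^2}, with large-age
#' behaviour \eqn{c / x^2} (slope -2).
#'
#' @param x Ages in years, positive (0 allowed: continuous extension).
#' @param dist A [frailty_distributions] object.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @param rel_tol Relative tolerance for the quadrature route.
#' @return Rates per person-year.
#' @export
hazard_from_density <- function(x, dist, method = c("closed_form", "quadrature"),
                                rel_tol = 1e-8) {
  stopifnot(inherits(dist, "frailty_dist"))
  method <- match.arg(method)
  if (any(x < 0)) stop("age must be non-negative", call. = FALSE)
  if (method == "quadrature") {
    return(vapply(x, .hazard_quadrature, numeric(1L), dist = dist,
                  rel_tol = rel_tol))
  }
  switch(dist$kind,
    point_mass = dist$mass * dist$r * exp(-dist$r * x),
    reciprocal = {
      out <- numeric(length(x)); z <- x == 0
      out[z] <- dist$c * (dist$r_max - dist$r_min)
      out[!z] <- dist$c *
        (exp(-dist$r_min * x[!z]) - exp(-dist$r_max * x[!z])) / x[!z]
      out
    },
    uniform = {
      out <- numeric(length(x)); z <- x == 0
      out[z] <- dist$c * dist$r_max^2 / 2
      xx <- x[!z]
      out[!z] <- dist$c *
        (1 - exp(-dist$r_max * xx) * (1 + dist$r_max * xx)) / xx^2
      out
    },
    stop(sprintf("no hazard rule for family '%s'", dist$kind), call. = FALSE)
  )
}

.hazard_quadrature <- function(x, dist, rel_tol = 1e-8) {
  switch(dist$kind,
    point_mass = dist$mass * dist$r * exp(-dist$r * x),
    reciprocal = {
      # substitute u = ln r: integral c r e^{-rx} / r dr = c e^{-e^u x} e^u du / e^u
      f <- function(u) exp(u) * exp(-exp(u) * x)
      dist$c * stats::integrate(f, log(dist$r_min), log(dist$r_max),
                                rel.tol = rel_tol)$value
    },
    uniform = {
      f <- function(r) r * exp(-r * x)
      dist$c * stats::integrate(f, 0, dist$r_max, rel.tol = rel_tol)$value
    },
    stop("unsupported family for quadrature", call. = FALSE)
  )
}

#' Validity region of the constant (flat) approximation
#'
#' The bending hazard is approximately the constant `mu1 * r_max` where the
#' product `r_max * x` is smaller than 1 (strict inequality).
#'
#' @param x Ages in years, non-negative.
#' @param mu1,r_max Bending-curve parameters (see [hazard_bending()]).
#' @return Data frame with columns `x`, `valid` (is `r_max * x < 1`?) and
#'   `rate_approx` (`mu1 * r_max`).
#' @export
constant_approx_region <- function(x, mu1, r_max) {
  stopifnot(mu1 > 0, r_max > 0, all(x >= 0))
  data.frame(x = x, valid = r_max * x < 1, rate_approx = mu1 * r_max)
}

#' Fit the bending trajectory
#'
#' Least-squares fit of the bending curve
#' \eqn{\mu(x) = (\mu_1/x)(1 - e^{-r_{max} x})} over `(mu1, r_max)`, on the
#' log scale by default (consistent with the rest of the model family) or on
#' the natural scale.  Optimization runs over `(ln mu1, ln r_max)` with
#' `r_max` bounded in `r_max_bounds`, from five log-spaced `r_max` starts
#' around an initial guess (`mu1` from the closed-form one-parameter
#' estimator on the last three points; `r_max` from the first-bin rate
#' divided by that `mu1`).
#'
#' For data that are log-log linear with slope -1 the two parameters are not
#' jointly identifiable (the curve straightens as `r_max` grows); such fits
#' end on the upper `r_max` bound and are flagged `straight_line_regime`.
#'
#' @inheritParams fit_loglog_linear
#' @param fit_scale `"log"` (default) or `"natural"`.
#' @param r_max_bounds Search bounds for `r_max`, per year.
#' @return An object of class `"bending_fit"` with elements `mu1`, `r_max`,
#'   `rss`, `r2_adjusted` (on the fit scale, 2 fitted parameters),
#'   `fit_scale`, `straight_line_regime`, `n`, `data`.
#' @export
fit_bending <- function(atm, fit_scale = c("log", "natural"),
                        r_max_bounds = c(1e-4, 1e4), drop_undefined = FALSE) {
  fit_scale <- match.arg(fit_scale)
  d <- .log_points(atm, drop_undefined)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 points for the bending fit", call. = FALSE)

  obs <- if (fit_scale == "log") d$lnmu else d$rate
  objective <- function(theta) {
    mu1 <- exp(theta[1L]); r_max <- exp(theta[2L])
    h <- hazard_bending(d$x, mu1, r_max)
    if (any(h <= 0) || any(!is.finite(h))) return(1e300)
    pred <- if (fit_scale == "log") log(h) else h
    sum((obs - pred)^2)
  }

  last <- d[order(d$x), ][max(1L, n - 2L):n, ]
  mu1_0 <- exp(mean(last$lnmu + last$lnx))
  r_max_0 <- min(max(d$rate[which.min(d$x)] / mu1_0, r_max_bounds[1L]),
                 r_max_bounds[2L])
  starts <- pmin(pmax(r_max_0 * 10^seq(-2, 2), r_max_bounds[1L]),
                 r_max_bounds[2L])
  lb <- c(-Inf, log(r_max_bounds[1L]))
  ub <- c(Inf, log(r_max_bounds[2L]))
  best <- NULL
  for (s in unique(starts)) {
    res <- tryCatch(
      stats::optim(c(log(mu1_0), log(s)), objective, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = 1e4, maxit = 500L)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    # polish with Nelder-Mead inside the bounds
    res2 <- stats::optim(res$par, function(th) {
      th[2L] <- min(max(th[2L], lb[2L]), ub[2L]); objective(th)
    }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000L))
    res2$par[2L] <- min(max(res2$par[2L], lb[2L]), ub[2L])
    if (is.null(best) || res2$value < best$value) best <- res2
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("bending fit failed to converge from all starts", call. = FALSE)
  }
  mu1 <- exp(best$par[1L]); r_max <- exp(best$par[2L])
  ss_total <- sum((obs - mean(obs))^2)
  structure(
    list(
      mu1 = mu1, r_max = r_max, rss = best$value,
      r2_adjusted = adjusted_r2(best$value, ss_total, n, 2L),
      fit_scale = fit_scale,
      straight_line_regime = r_max >= r_max_bounds[2L] * 0.999,
      n = n, data = d, model = "bending"
    ),
    class = "bending_fit"
  )
}

#' @export
print.bending_fit <- function(x, ...) {
  cat(sprintf(
    "Bending fit mu(x) = (mu1/x)(1 - exp(-r_max x)) [%s scale, n = %d]\n  mu1 = %.5g, r_max = %.5g per year%s\n  RSS = %.4g, adjusted R2 = %.4f\n",
    x$fit_scale, x$n, x$mu1, x$r_max,
    if (x$straight_line_regime) " (upper bound: straight-line regime)" else "",
    x$rss, x$r2_adjusted))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (rss / (n - k)) / (ss_total / (n - 1))` with `k` the number of
#' fitted parameters, so the residual degrees of freedom are `n - k`.  For
#' the one-parameter inverse-proportion model this reduces to the plain
#' coefficient of determination (its single scale parameter uses one degree
#' of freedom, like an arithmetic mean); for the two-parameter log-log linear
#' model it equals the usual adjusted R-squared.
#'
#' @param rss Residual sum of squares.
#' @param ss_total Total sum of squares about the mean.
#' @param n Number of points.
#' @param k Number of fitted parameters.
#' @return Adjusted R-squared; may be negative for models that fit worse
#'   than the trivial constant model.
#' @export
adjusted_r2 <- function(rss, ss_total, n, k) {
  if (ss_total <= 0) return(NA_real_)
  1 - (rss / (n - k)) / (ss_total / (n - 1))
}
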