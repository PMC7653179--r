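# Historical childhood-mortality models ----------------------------------
#
# Four published model shapes for the mortality decline after birth, all fit
# by least squares on the log scale (matching the treatment of the log-log
# model family) on a complete trajectory:
#
#   EXP      mu(x) = a exp(-b x)             (Gompertz-type decline, 2 par)
#   BP       mu(x) = 3 b ln^2(1 + x/s)/(x+s) (hazard implied by a cumulative
#                                             infant-deaths curve linear in
#                                             the cubed log of age, with free
#                                             time scale s; canonical form
#                                             fixes s at one day, 2 par)
#   HP       mu(x) = A^((x + B)^C)           (childhood term of the
#                                             Heligman-Pollard law, 3 par)
#   WEIBULL  mu(x) = a x^s, s > -1           (Weibull hazard: power law with
#                                             log-log slope above -1, 2 par)
#
# The Weibull hazard coincides with the two-parameter log-log linear model
# whenever the unconstrained slope is above -1; steeper data pin the slope at
# the bound and the fit is flagged.

.historical_k <- c(EXP = 2L, BP = 2L, HP = 3L, WEIBULL = 2L)

#' Fit a historical childhood-mortality model
#'
#' @inheritParams fit_loglog_linear
#' @param model One of `"EXP"`, `"BP"`, `"HP"`, `"WEIBULL"` (see Details in
#'   the package vignette).
#' @return An object of class `"historical_fit"`: `model_name`, named
#'   `parameters`, `rss` and `r2_adjusted` on the log scale,
#'   `constraint_active` (Weibull slope bound), `k` (parameter count), `n`,
#'   `data`.
#' @export
fit_historical <- function(atm, model = c("EXP", "BP", "HP", "WEIBULL"),
                           drop_undefined = FALSE) {
  model <- match.arg(model)
  d <- .log_points(atm, drop_undefined)
  n <- nrow(d)
  k <- .historical_k[[model]]
  if (n < k + 1L) {
    stop(sprintf("need at least %d points to fit %s", k + 1L, model),
         call. = FALSE)
  }
  fit <- switch(model,
    EXP = .fit_exp(d),
    BP = .fit_bp(d),
    HP = .fit_hp(d),
    WEIBULL = .fit_weibull(d)
  )
  ss_total <- sum((d$lnmu - mean(d$lnmu))^2)
  structure(
    list(model_name = model, parameters = fit$parameters, rss = fit$rss,
         r2_adjusted = adjusted_r2(fit$rss, ss_total, n, k),
         constraint_active = isTRUE(fit$constraint_active),
         k = k, n = n, data = d, predict_lnmu = fit$predict_lnmu),
    class = "historical_fit"
  )
}

.fit_exp <- function(d) {
  fit <- stats::lm(lnmu ~ x, data = d)
  cf <- stats::coef(fit)
  list(parameters = list(a = exp(unname(cf[1L])), b = -unname(cf[2L])),
       rss = sum(stats::resid(fit)^2),
       predict_lnmu = function(x) unname(cf[1L] + cf[2L] * x))
}

.fit_weibull <- function(d) {
  fit <- stats::lm(lnmu ~ lnx, data = d)
  slope <- unname(stats::coef(fit)[2L])
  if (slope > -1) {
    cf <- stats::coef(fit)
    return(list(
      parameters = list(a = exp(unname(cf[1L])), slope = slope,
                        shape = slope + 1),
      rss = sum(stats::resid(fit)^2),
      predict_lnmu = function(x) unname(cf[1L]) + slope * log(x)
    ))
  }
  # slope bound active: the power-law exponent of a Weibull hazard is
  # shape - 1 > -1; pin at the boundary, where the scale has the same closed
  # form as the inverse-proportion estimator
  warning("Weibull slope bound -1 active: boundary solution returned",
          call. = FALSE)
  lna <- mean(d$lnmu + d$lnx)
  list(parameters = list(a = exp(lna), slope = -1, shape = 0),
       rss = sum((d$lnmu - (lna - d$lnx))^2),
       constraint_active = TRUE,
       predict_lnmu = function(x) lna - log(x))
}

.fit_bp <- function(d) {
  # profile the level: given scale s, ln mu = const + 2 ln ln(1+x/s) - ln(x+s)
  prss <- function(ln_s) {
    s <- exp(ln_s)
    w <- 2 * log(log1p(d$x / s)) - log(d$x + s)
    const <- mean(d$lnmu - w)
    sum((d$lnmu - const - w)^2)
  }
  grid <- seq(log(1e-5), log(10), length.out = 200L)
  v <- vapply(grid, prss, numeric(1L))
  i <- which.min(v)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(prss, c(lo, hi), tol = 1e-12)
  s <- exp(opt$minimum)
  w <- 2 * log(log1p(d$x / s)) - log(d$x + s)
  const <- mean(d$lnmu - w)
  list(parameters = list(b = exp(const) / 3, s = s),
       rss = opt$objective,
       predict_lnmu = function(x) const + 2 * log(log1p(x / s)) - log(x + s))
}

.fit_hp <- function(d) {
  # ln mu = ln(A) (x + B)^C with ln(A) < 0; profile ln(A) out (linear in the
  # weights w = (x+B)^C), optimize (ln B, ln C) from a small multi-start grid
  prss <- function(theta) {
    B <- exp(theta[1L]); C <- exp(theta[2L])
    w <- (d$x + B)^C
    if (any(!is.finite(w))) return(1e300)
    lnA <- sum(w * d$lnmu) / sum(w^2)
    if (!is.finite(lnA) || lnA >= 0) lnA <- min(lnA, -1e-12)
    sum((d$lnmu - lnA * w)^2)
  }
  starts <- expand.grid(lnB = log(c(0.003, 0.03, 0.3)),
                        lnC = log(c(0.05, 0.15, 0.4)))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    res <- stats::optim(as.numeric(starts[j, ]), prss, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 3000L))
    if (is.null(best) || res$value < best$value) best <- res
  }
  B <- exp(best$par[1L]); C <- exp(best$par[2L])
  w <- (d$x + B)^C
  lnA <- min(sum(w * d$lnmu) / sum(w^2), -1e-12)
  list(parameters = list(A = exp(lnA), B = B, C = C),
       rss = best$value,
       predict_lnmu = function(x) lnA * (x + B)^C)
}

#' @export
print.historical_fit <- function(x, ...) {
  pars <- paste(sprintf("%s = %.5g", names(x$parameters),
                        unlist(x$parameters)), collapse = ", ")
  cat(sprintf("%s fit (log scale, n = %d): %s\n  RSS = %.4g, adjusted R2 = %.4f%s\n",
              x$model_name, x$n, pars, x$rss, x$r2_adjusted,
              if (x$constraint_active) " [slope bound active]" else ""))
  invisible(x)
}

#' Compare hazard models on one trajectory
#'
#' Fits the requested models on the same complete trajectory and ranks them
#' by adjusted R-squared computed with a common rule
#' (see [adjusted_r2()]): the one-parameter inverse proportion, the
#' two-parameter log-log line, the bending curve, and the four historical
#' models.  A failing fit is recorded in its row and the comparison is still
#' returned.
#'
#' @inheritParams fit_loglog_linear
#' @param models Character vector from `"INVPROP"`, `"LINEAR"`, `"BENDING"`,
#'   `"EXP"`, `"BP"`, `"HP"`, `"WEIBULL"`.
#' @return A data frame of class `"model_comparison"` with columns `model`,
#'   `k`, `parameters`, `rss`, `r2_adjusted`, `rank`, `error`, ordered by
#'   rank.
#' @export
compare_models <- function(atm,
                           models = c("INVPROP", "LINEAR", "BENDING",
                                      "EXP", "BP", "HP", "WEIBULL"),
                           drop_undefined = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  d <- .log_points(atm, drop_undefined)
  ss_total <- sum((d$lnmu - mean(d$lnmu))^2)
  n <- nrow(d)
  one <- function(model) {
    res <- tryCatch(switch(model,
      INVPROP = {
        f <- fit_inverse_proportion(atm, drop_undefined = drop_undefined)
        list(k = 1L, pars = sprintf("mu1 = %.5g", f$mu1), rss = f$rss)
      },
      LINEAR = {
        f <- fit_loglog_linear(atm, drop_undefined = drop_undefined)
        list(k = 2L,
             pars = sprintf("intercept = %.5g, gamma = %.5g", f$intercept, f$gamma),
             rss = f$rss)
      },
      BENDING = {
        f <- fit_bending(atm, drop_undefined = drop_undefined)
        list(k = 2L,
             pars = sprintf("mu1 = %.5g, r_max = %.5g", f$mu1, f$r_max),
             rss = f$rss)
      },
      {
        f <- suppressWarnings(
          fit_historical(atm, model, drop_undefined = drop_undefined))
        list(k = f$k,
             pars = paste(sprintf("%s = %.5g", names(f$parameters),
                                  unlist(f$parameters)), collapse = ", "),
             rss = f$rss)
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(model = model, k = NA_integer_, parameters = NA_character_,
                        rss = NA_real_, r2_adjusted = NA_real_,
                        error = conditionMessage(res), stringsAsFactors = FALSE))
    }
    data.frame(model = model, k = res$k, parameters = res$pars, rss = res$rss,
               r2_adjusted = adjusted_r2(res$rss, ss_total, n, res$k),
               error = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(models, one))
  out$rank <- rank(-out$r2_adjusted, ties.method = "min", na.last = "keep")
  out <- out[order(out$rank), c("model", "k", "parameters", "rss",
                                "r2_adjusted", "rank", "error")]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (adjusted R2, log scale):\n")
  y <- as.data.frame(x)
  y$r2_adjusted <- round(y$r2_adjusted, 4)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
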