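# Shared fixtures, all generated in code.

who9 <- standard_age_grid(0, 10)

# A trajectory exactly on ln mu = intercept + gamma ln x at the nine WHO
# midpoints, plus optional Gaussian log-scale noise.
line_atm <- function(gamma = -1, intercept = log(0.0014), sigma = 0,
                     x = who9$midpoint, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lnmu <- intercept + gamma * log(x) + stats::rnorm(length(x), 0, sigma)
  as_atm(data.frame(x = x, rate = exp(lnmu)))
}

# A trajectory with slope exactly -1 after OLS, but nonzero residuals:
# noise is projected orthogonal to (1, ln x).
line_atm_exact_slope <- function(gamma = -1, intercept = log(0.0014),
                                 seed = 42, x = who9$midpoint) {
  set.seed(seed)
  e <- stats::rnorm(length(x), 0, 0.1)
  e <- stats::resid(stats::lm(e ~ log(x)))
  as_atm(data.frame(x = x, rate = exp(intercept + gamma * log(x) + e)))
}

# A random multi-population, multi-year record table on the nine WHO bins.
random_records <- function(n_pop = 3, n_year = 2, causes = "ALL", seed = 1) {
  set.seed(seed)
  cells <- expand.grid(
    population = sprintf("C%02d", seq_len(n_pop)),
    year = 2000L + seq_len(n_year) - 1L,
    cause = causes, stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(cells)), function(i) {
    living <- as.numeric(sample(5e4:5e5, nrow(who9), replace = TRUE))
    data.frame(
      population = cells$population[i], year = cells$year[i],
      cause = cells$cause[i],
      bin_label = who9$label, lower = who9$lower, upper = who9$upper,
      deaths = as.numeric(stats::rpois(nrow(who9), lambda = pmax(1, living * 1e-4))),
      living = living, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
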