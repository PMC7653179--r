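# Frailty sampling, cohort simulation, expected-count oracles, presets

test_that("frailty sampling honors each family", {
  expect_equal(sample_frailties(frailty_point_mass(0.1), 5, seed = 1),
               rep(0.1, 5))
  mix0 <- frailty_mixture(frailty_point_mass(0.1), 0)
  expect_equal(sample_frailties(mix0, 100, seed = 1), rep(0, 100))

  # reciprocal: empirical CDF matches the log-uniform inverse-CDF oracle
  d <- frailty_reciprocal(1e-3, 1e2)
  r <- sample_frailties(d, 1e5, seed = 7)
  expect_true(all(r > 1e-3 & r <= 1e2))
  ln_unif_cdf <- function(q) {
    pmin(pmax(log(q / 1e-3) / log(1e2 / 1e-3), 0), 1)
  }
  ks <- suppressWarnings(stats::ks.test(r, ln_unif_cdf))
  expect_lt(unname(ks$statistic), 0.01)

  # mixture: impaired share close to p_impaired
  mix <- frailty_mixture(frailty_uniform(2), 0.3)
  rm <- sample_frailties(mix, 1e5, seed = 8)
  expect_close(mean(rm > 0), 0.3, 0.01)
})

test_that("a cohort without risks records no deaths and constant denominators", {
  spec <- cohort_spec(1000, frailty_mixture(frailty_point_mass(0.5), 0),
                      seed = 2)
  rec <- simulate_cohort(spec, who9)
  expect_true(all(rec$deaths == 0))
  expect_true(all(rec$living == 1000))
})

test_that("homogeneous cohort deaths match the binomial expectation", {
  n <- 1e6
  spec <- cohort_spec(n, frailty_point_mass(0.1), seed = 3)
  rec <- simulate_cohort(spec, standard_age_grid(0, 10))
  d_year1 <- sum(rec$deaths[rec$upper <= 1])
  p <- 1 - exp(-0.1)
  expect_close(d_year1, n * p, 3 * sqrt(n * p * (1 - p)))
})

test_that("deaths plus survivors conserve the cohort, cell by cell", {
  spec <- cohort_spec(5e4, frailty_uniform(2, mass = 0.5),
                      populations = c("A", "B"), years = 2000:2001, seed = 4)
  rec <- simulate_cohort(spec, who9)
  for (cell in split(rec, paste(rec$population, rec$year))) {
    last <- which.max(cell$lower)
    survivors <- cell$living[last] - cell$deaths[last]
    expect_equal(sum(cell$deaths) + survivors, 5e4)
    # living counts are the survivors entering each bin
    expect_equal(cell$living[-1L], cell$living[-nrow(cell)] - cell$deaths[-nrow(cell)])
  }
})

test_that("simulation is seed-deterministic and cell streams are stable", {
  spec <- cohort_spec(1e4, frailty_uniform(1, mass = 0.1),
                      populations = c("A", "B"), years = 2000L, seed = 5)
  expect_identical(simulate_cohort(spec, who9), simulate_cohort(spec, who9))

  # dropping population A must not change B's records
  spec_b <- cohort_spec(1e4, frailty_uniform(1, mass = 0.1),
                        populations = "B", years = 2000L, seed = 5)
  both <- simulate_cohort(spec, who9)
  only_b <- simulate_cohort(spec_b, who9)
  b_rows <- both[both$population == "B", ]
  rownames(b_rows) <- NULL
  expect_identical(b_rows, only_b)

  # a different master seed changes the draw
  spec2 <- cohort_spec(1e4, frailty_uniform(1, mass = 0.1),
                       populations = c("A", "B"), years = 2000L, seed = 6)
  expect_false(identical(simulate_cohort(spec2, who9), both))
})

test_that("expected counts match closed forms and conserve mass", {
  n <- 1e7
  spec <- cohort_spec(n, frailty_point_mass(0.2), seed = 1)
  rec <- expected_counts(spec, who9, round_counts = FALSE)
  # point mass: deaths in [A, B) are n (e^(-rA) - e^(-rB))
  expect_equal(rec$deaths,
               n * (exp(-0.2 * rec$lower) - exp(-0.2 * rec$upper)),
               tolerance = 1e-9)
  expect_equal(rec$living, n * exp(-0.2 * rec$lower), tolerance = 1e-9)

  # reciprocal with wide support: deaths proportional to log(B/A)
  dist <- frailty_mixture(frailty_reciprocal(1e-6, 1e6), 0.02)
  spec2 <- cohort_spec(n, dist, seed = 1)
  grid <- age_grid(c(1, 2, 4))
  rec2 <- expected_counts(spec2, grid, round_counts = FALSE)
  expect_equal(rec2$deaths[1L], rec2$deaths[2L], tolerance = 1e-4)
})

test_that("simulated cohorts converge to the expected counts", {
  n <- 2e5
  dist <- frailty_mixture(frailty_uniform(2), 0.05)
  exp_rec <- expected_counts(cohort_spec(n, dist), who9, round_counts = FALSE)
  sums <- matrix(0, nrow(who9), 2L)
  n_seed <- 50L
  for (s in seq_len(n_seed)) {
    r <- simulate_cohort(cohort_spec(n, dist, seed = s), who9)
    sums <- sums + cbind(r$deaths, r$living)
  }
  mean_deaths <- sums[, 1L] / n_seed
  # three standard errors of the replicate mean, per bin
  se <- sqrt(pmax(exp_rec$deaths, 1)) / sqrt(n_seed)
  expect_true(all(abs(mean_deaths - exp_rec$deaths) < 3 * se + 1))
  mean_living <- sums[, 2L] / n_seed
  expect_true(all(abs(mean_living - exp_rec$living) / exp_rec$living < 1e-3))
})

test_that("count rounding at the default cohort size is inconsequential", {
  spec <- scenario_preset("inverse_proportion")
  atm_r <- build_atm(halley_aggregate(expected_counts(spec, who9)), c(0, 10))
  atm_c <- build_atm(
    halley_aggregate(expected_counts(spec, who9, round_counts = FALSE)),
    c(0, 10))
  g_r <- fit_loglog_linear(atm_r)$gamma
  g_c <- fit_loglog_linear(atm_c)$gamma
  expect_lt(abs(g_r - g_c) / abs(g_c), 1e-3)
})

test_that("presets encode their advertised trajectory shapes", {
  expect_error(scenario_preset("no_such"), "inverse_proportion")

  hom <- scenario_preset("homogeneous")
  expect_equal(hom$dist$kind, "point_mass")
  expect_equal(hom$dist$mass, 1)

  # inverse_proportion: slope -1 within 0.05 on expected counts
  sp1 <- scenario_preset("inverse_proportion")
  atm1 <- build_atm(halley_aggregate(expected_counts(sp1, who9)), c(0, 10))
  expect_close(fit_loglog_linear(atm1)$gamma, -1, 0.05)

  # perinatal_uniform: slope -2 within 0.1 on [1, 10)
  sp2 <- scenario_preset("perinatal_uniform")
  atm2 <- build_atm(halley_aggregate(expected_counts(sp2, who9)), c(1, 10))
  expect_close(fit_loglog_linear(atm2)$gamma, -2, 0.1)

  # neoplasm_flat: age-independence on [1, 10), slope within 0.05 of 0
  sp3 <- scenario_preset("neoplasm_flat")
  atm3 <- build_atm(halley_aggregate(expected_counts(sp3, who9)), c(1, 10))
  expect_close(fit_loglog_linear(atm3)$gamma, 0, 0.05)

  # bending: flat early, inverse-proportional late
  sp4 <- scenario_preset("bending")
  atm4 <- build_atm(halley_aggregate(expected_counts(sp4, who9)), c(0, 10))
  early <- atm4$rate[1:2]
  expect_lt(abs(early[2] / early[1] - 1), 0.1)   # nearly constant
  late <- atm4[atm4$x >= 2, ]
  late_slope <- stats::coef(stats::lm(log(rate) ~ log(x), late))[2L]
  expect_close(unname(late_slope), -1, 0.1)
})

test_that("expected counts stay valid count tables after rounding", {
  spec <- scenario_preset("neoplasm_flat")
  rec <- expected_counts(spec, who9)
  expect_true(all(rec$deaths >= 0))
  expect_true(all(rec$deaths == round(rec$deaths)))
  expect_true(all(rec$deaths <= rec$living))
})
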