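# End-to-end pipeline: simulate/load -> aggregate -> ATM -> fit -> report --

#' Configure an analysis pipeline run
#'
#' @param scenario Name of a [scenario_preset()] to generate data from, or
#'   `NULL` when `input` is given.
#' @param input Path to a canonical count-table CSV (see
#'   [read_count_table()]), or `NULL` when `scenario` is given.
#' @param mode For scenarios: `"expected"` (deterministic expected counts) or
#'   `"simulate"` (stochastic cohort).
#' @param causes Causes to analyze per chapter; `NULL` analyzes every cause
#'   present.  Total mortality (all causes pooled) is always analyzed.
#' @param aggregate_name Label of the pooled population aggregate.
#' @param age_range Analysis window in years for total mortality.
#' @param infant_range,child_range The two chapter-analysis windows.
#' @param alpha Significance level for all tests.
#' @param fit_scale Scale for the bending fit.
#' @param strict Refuse incomplete trajectories (`TRUE`) or drop undefined
#'   points (`FALSE`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed (scenarios only).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = NULL, input = NULL,
                            mode = c("expected", "simulate"),
                            causes = NULL, aggregate_name = "PALL",
                            age_range = c(0, 10),
                            infant_range = c(0, 1), child_range = c(1, 10),
                            alpha = 0.05, fit_scale = c("log", "natural"),
                            strict = TRUE, out_dir = "atmort-report",
                            seed = 1L) {
  mode <- match.arg(mode)
  fit_scale <- match.arg(fit_scale)
  if (is.null(scenario) == is.null(input)) {
    stop("give exactly one of 'scenario' or 'input'", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(scenario = scenario, input = input, mode = mode, causes = causes,
         aggregate_name = aggregate_name, age_range = age_range,
         infant_range = infant_range, child_range = child_range,
         alpha = alpha, fit_scale = fit_scale, strict = strict,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow: acquire count records (from a scenario
#' preset or a CSV table), Halley-aggregate, build trajectories, fit and test
#' the model family, and write a report bundle to `config$out_dir`:
#'
#' * `summary_fits.csv`: per population, the linearity p-value, `gamma` with
#'   confidence interval, adjusted R2 of the linear model, Rb2 of the
#'   inverse proportion, their difference, and the nested F-test p-value for
#'   total mortality on `age_range`.
#' * `chapter_fits.csv`: per cause, total deaths and share, the
#'   trajectory-constructible flag, and the slopes with age-independence and
#'   slope -1 tests on the infant and child windows.
#' * `model_comparison.csv`: ranked adjusted R2 of all models on the pooled
#'   total-mortality trajectory.
#' * `results.json`: all of the above at full precision, keyed by
#'   population, cause, interval and model.
#' * `manifest.json`: configuration, seed, package version and record
#'   counts.
#'
#' CSV tables print slopes to 3 decimals and R2 to 4 (full precision lives
#' in the JSON).  Any stage failure removes the partial bundle and aborts
#' with the stage name.  Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  created <- character(0)
  fail <- function(stage, e) {
    unlink(created)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  grid <- standard_age_grid(0, max(config$age_range[2L],
                                   config$child_range[2L]))
  records <- stage("acquire", {
    if (!is.null(config$scenario)) {
      spec <- scenario_preset(config$scenario, seed = config$seed)
      if (config$mode == "expected") expected_counts(spec, grid)
      else simulate_cohort(spec, grid)
    } else {
      read_count_table(config$input)
    }
  })

  stage("validate", {
    if (!is.null(config$causes)) {
      missing <- setdiff(config$causes, unique(records$cause))
      if (length(missing)) {
        stop(sprintf("cause filter names unknown cause(s): %s",
                     paste(missing, collapse = ", ")))
      }
    }
    invisible(NULL)
  })

  drop_undefined <- !config$strict
  populations <- sort(unique(records$population))
  alpha <- config$alpha

  summary_row <- function(pop_filter, label) {
    agg <- halley_aggregate(records, populations = pop_filter,
                            aggregate_name = label)
    atm <- build_atm(agg, config$age_range)
    if (!is_complete(atm) && config$strict) {
      return(data.frame(population = label, atm = FALSE, n = NA, p_linearity = NA,
                        gamma = NA, ci_low = NA, ci_high = NA, r2_adj = NA,
                        r2_b = NA, r2_b_minus_r2_adj = NA, p_invprop_f = NA))
    }
    lin <- fit_loglog_linear(atm, drop_undefined = drop_undefined)
    inv <- fit_inverse_proportion(atm, drop_undefined = drop_undefined)
    data.frame(
      population = label, atm = TRUE, n = lin$n,
      p_linearity = test_linearity_quadratic(atm, alpha, drop_undefined)$p_value,
      gamma = lin$gamma,
      ci_low = unname(lin$ci_gamma[1L]), ci_high = unname(lin$ci_gamma[2L]),
      r2_adj = lin$r2_adjusted, r2_b = inv$r2_b,
      r2_b_minus_r2_adj = inv$r2_b - lin$r2_adjusted,
      p_invprop_f = nested_f_test(lin, inv, alpha)$p_value
    )
  }

  tab_summary <- stage("summary_fits", {
    rows <- lapply(populations, function(p) summary_row(p, p))
    if (length(populations) > 1L) {
      rows <- c(rows, list(summary_row(populations, config$aggregate_name)))
    } else {
      # single population: the pooled aggregate is the population itself
      rows[[1L]]$population <- populations[1L]
    }
    do.call(rbind, rows)
  })

  causes <- if (is.null(config$causes)) sort(unique(records$cause)) else config$causes
  tab_chapters <- stage("chapter_fits", {
    total_deaths <- sum(records$deaths)
    rows <- lapply(causes, function(cs) {
      agg <- halley_aggregate(records, causes = cs,
                              aggregate_name = config$aggregate_name)
      sum_d <- sum(agg$counts$deaths)
      window_fit <- function(range) {
        atm <- build_atm(agg, range)
        if (!is_complete(atm)) {
          return(list(gamma = NA_real_, p0 = NA_real_, pm1 = NA_real_))
        }
        f <- fit_loglog_linear(atm)
        list(gamma = f$gamma,
             p0 = test_fixed_slope(f, 0, alpha)$p_value,
             pm1 = test_fixed_slope(f, -1, alpha)$p_value)
      }
      atm_flag <- is_complete(build_atm(agg, config$infant_range)) &&
        is_complete(build_atm(agg, config$child_range))
      w1 <- window_fit(config$infant_range)
      w2 <- window_fit(config$child_range)
      data.frame(
        cause = cs, deaths = sum_d,
        proportion = sum_d / total_deaths, atm = atm_flag,
        gamma1 = w1$gamma, p_gamma1_eq_0 = w1$p0, p_gamma1_eq_m1 = w1$pm1,
        gamma2 = w2$gamma, p_gamma2_eq_0 = w2$p0, p_gamma2_eq_m1 = w2$pm1
      )
    })
    do.call(rbind, rows)
  })

  tab_models <- stage("model_comparison", {
    agg <- halley_aggregate(records, aggregate_name = config$aggregate_name)
    atm <- build_atm(agg, config$age_range)
    if (!is_complete(atm) && config$strict) {
      # not constructible under the strict zero-death rule
      data.frame(model = character(0), k = integer(0),
                 parameters = character(0), rss = numeric(0),
                 r2_adjusted = numeric(0), rank = integer(0),
                 error = character(0))
    } else {
      suppressWarnings(
        as.data.frame(compare_models(atm, drop_undefined = drop_undefined))
      )
    }
  })

  stage("report", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, name, round_map = NULL) {
      if (!is.null(round_map)) {
        for (col in names(round_map)) {
          if (col %in% names(x)) x[[col]] <- round(x[[col]], round_map[[col]])
        }
      }
      path <- file.path(out_dir, name)
      utils::write.csv(x, path, row.names = FALSE, na = "")
      created <<- c(created, path)
    }
    # paper-style display precision: slopes 3 decimals, R2 4
    wcsv(tab_summary, "summary_fits.csv",
         list(p_linearity = 4, gamma = 3, ci_low = 3, ci_high = 3,
              r2_adj = 4, r2_b = 4, r2_b_minus_r2_adj = 4, p_invprop_f = 4))
    wcsv(tab_chapters, "chapter_fits.csv",
         list(proportion = 4, gamma1 = 3, p_gamma1_eq_0 = 4,
              p_gamma1_eq_m1 = 4, gamma2 = 3, p_gamma2_eq_0 = 4,
              p_gamma2_eq_m1 = 4))
    wcsv(tab_models, "model_comparison.csv", list(r2_adjusted = 4))
    results <- list(summary_fits = tab_summary, chapter_fits = tab_chapters,
                    model_comparison = tab_models)
    jpath <- file.path(out_dir, "results.json")
    jsonlite::write_json(results, jpath, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
    created <<- c(created, jpath)
    cfg_echo <- unclass(config)
    cfg_echo$out_dir <- NULL   # keep the manifest location-independent
    manifest <- list(
      package = "atmort",
      version = as.character(utils::packageVersion("atmort")),
      config = cfg_echo,
      n_records = nrow(records),
      n_deaths = sum(records$deaths),
      populations = populations,
      causes = causes
    )
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    created <<- c(created, mpath)
  })

  invisible(list(summary_fits = tab_summary, chapter_fits = tab_chapters,
                 model_comparison = tab_models, files = created))
}

#' Lower limit of a susceptible subpopulation
#'
#' When mortality from a disease group is age-independent over an age range
#' (no extinction of a susceptible pool is visible), the total number of
#' deaths in that range is a lower limit for the size of the subpopulation
#' susceptible to the group: the pool must at least contain everyone who
#' died of it.
#'
#' @param total_deaths Deaths in the age range, non-negative.
#' @param total_living Living population, positive.
#' @return List with `proportion` (`deaths / living`) and `per_100k`
#'   (the same per 100,000 living).
#' @export
#' @examples
#' subpopulation_lower_limit(30, 1e6)  # at least 3 per 100,000 susceptible
subpopulation_lower_limit <- function(total_deaths, total_living) {
  if (total_living <= 0) stop("total_living must be positive", call. = FALSE)
  if (total_deaths < 0) stop("total_deaths must be non-negative", call. = FALSE)
  p <- total_deaths / total_living
  list(proportion = p, per_100k = p * 1e5)
}
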