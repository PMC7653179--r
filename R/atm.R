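# Age trajectories of mortality (ATM) ------------------------------------

#' Mortality rate per person-year in an age category
#'
#' The force of mortality at the representative age of a bin \eqn{[A, B)} is
#' estimated as \eqn{D / (L (B - A))}: deaths divided by person-years, where
#' the living count \eqn{L} passes through the age window of width
#' \eqn{B - A} years.
#'
#' @param deaths Non-negative death counts.
#' @param living Positive living-population counts.
#' @param width Bin widths \eqn{B - A} in years.
#' @return Rates per person-year.  Multiply by `1e5` for the conventional
#'   per-100,000 presentation scale.
#' @export
#' @examples
#' mortality_rate(10, 1000, 1)        # 0.01 per person-year
#' mortality_rate(10, 10000, 1 / 365) # 0.365 per person-year
mortality_rate <- function(deaths, living, width) {
  if (any(living <= 0)) stop("living must be positive", call. = FALSE)
  if (any(width <= 0)) stop("bin width must be positive", call. = FALSE)
  if (any(deaths < 0)) stop("deaths must be non-negative", call. = FALSE)
  deaths / (living * width)
}

.new_atm <- function(points, population, cause, age_range) {
  stopifnot(all(diff(points$x) > 0))
  attr(points, "population") <- population
  attr(points, "cause") <- cause
  attr(points, "age_range") <- age_range
  attr(points, "complete") <- all(points$defined)
  class(points) <- c("atm", "data.frame")
  points
}

#' Build an age trajectory of mortality
#'
#' Converts Halley-aggregated counts into an ordered series of
#' (representative age, mortality rate) points on `age_range`.  The
#' representative age is always the arithmetic midpoint of the bin.  A point
#' with zero deaths gets rate 0 and is flagged undefined (its log-scale value
#' does not exist); a trajectory is `complete` only when every point has at
#' least one death.
#'
#' @param agg A [halley_aggregate()] result.
#' @param age_range Numeric `(min, max)` in years; the aggregate's grid must
#'   cover it with bin boundaries at both ends.
#' @return An object of class `"atm"`: a data frame with columns `x`
#'   (midpoint age, years), `rate` (per person-year), `deaths`,
#'   `person_years` and `defined`, plus attributes `population`, `cause`,
#'   `age_range` and `complete`.
#' @export
build_atm <- function(agg, age_range = c(0, 10)) {
  stopifnot(inherits(agg, "halley_agg"), length(age_range) == 2L)
  g <- agg$grid
  sel <- g$lower >= age_range[1L] - 1e-12 & g$upper <= age_range[2L] + 1e-12
  if (!any(sel) ||
      min(g$lower[sel]) > age_range[1L] + 1e-12 ||
      max(g$upper[sel]) < age_range[2L] - 1e-12) {
    stop(sprintf("grid does not cover the age range [%g, %g)",
                 age_range[1L], age_range[2L]), call. = FALSE)
  }
  cnt <- agg$counts[sel, , drop = FALSE]
  gg <- g[sel, , drop = FALSE]
  points <- data.frame(
    x = gg$midpoint,
    rate = mortality_rate(cnt$deaths, cnt$living, gg$width),
    deaths = cnt$deaths,
    person_years = cnt$living * gg$width,
    defined = cnt$deaths > 0,
    stringsAsFactors = FALSE
  )
  .new_atm(points, agg$aggregate_name, agg$cause, age_range)
}

#' Coerce rates to an ATM object
#'
#' Builds a model-space trajectory directly from (age, rate) pairs, for
#' fitting theoretical curves or externally computed rates.  Count columns
#' are set to `NA`.
#'
#' @param x Data frame with columns `x` (age in years, strictly increasing)
#'   and `rate` (per person-year, positive).
#' @param population,cause Labels carried on the object.
#' @return An `"atm"` object; see [build_atm()].
#' @export
as_atm <- function(x, population = "synthetic", cause = "ALL") {
  stopifnot(is.data.frame(x), all(c("x", "rate") %in% names(x)))
  if (any(x$rate < 0)) stop("rates must be non-negative", call. = FALSE)
  points <- data.frame(
    x = x$x, rate = x$rate,
    deaths = if ("deaths" %in% names(x)) x$deaths else NA_real_,
    person_years = if ("person_years" %in% names(x)) x$person_years else NA_real_,
    defined = x$rate > 0,
    stringsAsFactors = FALSE
  )
  .new_atm(points, population, cause, range(x$x))
}

#' Is the trajectory complete?
#'
#' @param atm An `"atm"` object.
#' @return `TRUE` when every point has at least one death (all log-scale
#'   values defined).
#' @export
is_complete <- function(atm) isTRUE(attr(atm, "complete"))

# Points for log-scale fitting.  Strict mode refuses incomplete trajectories,
# mirroring the rule that a trajectory with an empty age category is not
# constructed; drop_undefined = TRUE instead drops the undefined points.
.log_points <- function(atm, drop_undefined = FALSE) {
  if (inherits(atm, "atm")) {
    pts <- as.data.frame(atm)
  } else if (is.data.frame(atm) && all(c("x", "rate") %in% names(atm))) {
    pts <- data.frame(x = atm$x, rate = atm$rate,
                      defined = atm$rate > 0, stringsAsFactors = FALSE)
  } else {
    stop("expected an 'atm' object or a data frame with columns x, rate",
         call. = FALSE)
  }
  if (!all(pts$defined)) {
    if (!drop_undefined) {
      stop(paste0(
        "trajectory has zero-death points, so log-scale values are undefined; ",
        "pass drop_undefined = TRUE to fit on the defined points only"
      ), call. = FALSE)
    }
    pts <- pts[pts$defined, , drop = FALSE]
  }
  data.frame(x = pts$x, rate = pts$rate,
             lnx = log(pts$x), lnmu = log(pts$rate))
}

#' Serialize an ATM to CSV
#'
#' @param atm An `"atm"` object.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_atm <- function(atm, file) {
  stopifnot(inherits(atm, "atm"))
  out <- data.frame(
    x_years = atm$x,
    rate_per_person_year = atm$rate,
    deaths = atm$deaths,
    person_years = atm$person_years,
    defined = atm$defined
  )
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.atm <- function(x, ...) {
  cat(sprintf(
    "ATM for %s (cause %s) on [%g, %g) years; %d points, %s\n",
    attr(x, "population"), attr(x, "cause"),
    attr(x, "age_range")[1L], attr(x, "age_range")[2L], nrow(x),
    if (is_complete(x)) "complete" else "INCOMPLETE (zero-death bins)"
  ))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Per-bin proportions of deaths by cause
#'
#' For each age category, the share of deaths attributed to each cause,
#' summed over all populations and years in `records`.  Within every bin with
#' at least one death the proportions sum to one; bins without any deaths are
#' flagged undefined.
#'
#' @param records A record data frame (see [read_count_table()]).
#' @param min_share Optional threshold: keep only causes whose share exceeds
#'   `min_share` in at least one bin (e.g. `0.01`).
#' @return Data frame with columns `bin_label`, `lower`, `midpoint`, `cause`,
#'   `deaths`, `proportion`, `defined`.
#' @export
chapter_proportions <- function(records, min_share = NULL) {
  .validate_records(records, integer_counts = FALSE)
  bins <- unique(records[, c("bin_label", "lower", "upper")])
  bins <- bins[order(bins$lower), , drop = FALSE]
  tab <- stats::aggregate(deaths ~ bin_label + cause, data = records, FUN = sum)
  tot <- stats::aggregate(deaths ~ bin_label, data = tab, FUN = sum)
  names(tot)[2L] <- "bin_total"
  tab <- merge(tab, tot, by = "bin_label")
  tab$proportion <- ifelse(tab$bin_total > 0, tab$deaths / tab$bin_total, NA_real_)
  tab$defined <- tab$bin_total > 0
  i <- match(tab$bin_label, bins$bin_label)
  tab$lower <- bins$lower[i]
  tab$midpoint <- (bins$lower[i] + bins$upper[i]) / 2
  if (!is.null(min_share)) {
    keep <- unique(tab$cause[!is.na(tab$proportion) & tab$proportion > min_share])
    tab <- tab[tab$cause %in% keep, , drop = FALSE]
  }
  tab <- tab[order(tab$lower, tab$cause),
             c("bin_label", "lower", "midpoint", "cause", "deaths",
               "proportion", "defined")]
  rownames(tab) <- NULL
  tab
}
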