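# Count tables: parsing, validation, Halley aggregation ------------------

.record_roles <- c("population", "year", "cause", "bin_label", "deaths", "living")

# Validate a canonical record table; returns it invisibly or stops with the
# offending row index.  integer_counts = FALSE admits real-valued expected
# counts (the deterministic oracle's unrounded mode).
.validate_records <- function(records, integer_counts = TRUE) {
  need <- c(.record_roles, "lower", "upper")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("records are missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- which(is.na(records$deaths) | records$deaths < 0 |
                 (integer_counts & records$deaths != round(records$deaths)))
  if (length(bad)) {
    stop(sprintf("row %d: deaths must be a non-negative integer (got %s)",
                 bad[1L], records$deaths[bad[1L]]), call. = FALSE)
  }
  bad <- which(is.na(records$living) | records$living <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: living must be positive (got %s)",
                 bad[1L], records$living[bad[1L]]), call. = FALSE)
  }
  bad <- which(records$deaths > records$living)
  if (length(bad)) {
    stop(sprintf("row %d: deaths (%s) exceed living (%s)",
                 bad[1L], records$deaths[bad[1L]], records$living[bad[1L]]),
         call. = FALSE)
  }
  invisible(records)
}

#' Read a death/living count table
#'
#' Reads a delimited text table of death and living-population counts per
#' (population, calendar year, cause, age category) cell, the canonical
#' exchange schema for WHO-style extracts.  Age categories are given either
#' as grid labels (column `bin_label`, e.g. `"[1d,7d)"`) or as bounds in days
#' (columns `age_lower_days`, `age_upper_days`); either way they must resolve
#' against the standard grid.
#'
#' @param file Path or connection to a CSV file (UTF-8, header row).
#' @param schema Named character vector mapping roles to column names in the
#'   file.  Roles: `population`, `year`, `cause`, `deaths`, `living`, and
#'   either `bin_label` or both `age_lower_days` and `age_upper_days`.
#'   Defaults to identity names.
#' @param grid Grid to resolve age categories against; defaults to the full
#'   standard grid.
#' @return A data frame of validated count records with columns `population`,
#'   `year`, `cause`, `bin_label`, `lower`, `upper`, `deaths`, `living`, in
#'   file row order.
#' @export
read_count_table <- function(file, schema = NULL,
                             grid = standard_age_grid(0, 95)) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  as_count_table(raw, schema = schema, grid = grid)
}

#' Coerce a data frame of counts to validated count records
#'
#' @param x Data frame with the columns described in [read_count_table()].
#' @inheritParams read_count_table
#' @return A validated record data frame; see [read_count_table()].
#' @export
as_count_table <- function(x, schema = NULL, grid = standard_age_grid(0, 95)) {
  pick <- function(role, required = TRUE) {
    col <- if (!is.null(schema) && role %in% names(schema)) schema[[role]] else role
    if (!col %in% names(x)) {
      if (required) {
        stop(sprintf("missing column for role '%s' (expected column '%s')",
                     role, col), call. = FALSE)
      }
      return(NULL)
    }
    x[[col]]
  }
  bin_label <- pick("bin_label", required = FALSE)
  if (is.null(bin_label)) {
    lo_d <- pick("age_lower_days", required = FALSE)
    hi_d <- pick("age_upper_days", required = FALSE)
    if (is.null(lo_d) || is.null(hi_d)) {
      stop("missing column for role 'bin_label' (or 'age_lower_days'/'age_upper_days')",
           call. = FALSE)
    }
    bins <- .match_bins_bounds(as.numeric(lo_d) / 365, as.numeric(hi_d) / 365,
                               grid)
  } else {
    bins <- .match_bins(as.character(bin_label), grid)
  }
  rec <- data.frame(
    population = as.character(pick("population")),
    year = as.integer(pick("year")),
    cause = as.character(pick("cause")),
    bin_label = bins$label,
    lower = bins$lower,
    upper = bins$upper,
    deaths = as.numeric(pick("deaths")),
    living = as.numeric(pick("living")),
    stringsAsFactors = FALSE
  )
  .validate_records(rec)
  rec
}

#' Write count records as a canonical CSV table
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' returns `x`.
#'
#' @param records A record data frame (see [read_count_table()]).
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_count_table <- function(records, file) {
  .validate_records(records)
  utils::write.csv(
    records[, .record_roles],
    file, row.names = FALSE, quote = TRUE
  )
  invisible(file)
}

#' Halley aggregation of count records
#'
#' Sums deaths and living counts per age category over all selected
#' populations, calendar years and causes, the classical device for removing
#' zero-death cells before rate construction: in each age interval the living
#' and the dead of more than one calendar year and more than one region are
#' added together.
#'
#' @param records A record data frame (see [read_count_table()]).
#' @param causes,populations,years Selection filters: `NULL` (keep all), a
#'   vector of values to keep, or a predicate function.
#' @param aggregate_name Population label for the aggregate (e.g. `"P14"`).
#' @return An object of class `"halley_agg"`: a list with the bin-level sums
#'   (`counts`), the resolved `grid`, the contributing `(population, year)`
#'   pairs (`provenance`), the `aggregate_name` and the collapsed `cause`
#'   label.
#' @export
halley_aggregate <- function(records, causes = NULL, populations = NULL,
                             years = NULL, aggregate_name = "AGG") {
  .validate_records(records, integer_counts = FALSE)
  keep <- function(values, filter) {
    if (is.null(filter)) rep(TRUE, length(values))
    else if (is.function(filter)) vapply(values, filter, logical(1L))
    else values %in% filter
  }
  sel <- keep(records$cause, causes) &
    keep(records$population, populations) &
    keep(records$year, years)
  if (!any(sel)) {
    stop("no records match the given cause/population/year filters",
         call. = FALSE)
  }
  r <- records[sel, , drop = FALSE]

  # All selected records must live on one consistent grid of disjoint bins.
  bins <- unique(r[, c("bin_label", "lower", "upper")])
  if (anyDuplicated(bins$bin_label)) {
    stop("mixed incompatible age bins: one label maps to several bounds",
         call. = FALSE)
  }
  bins <- bins[order(bins$lower), , drop = FALSE]
  if (any(bins$lower[-1L] < bins$upper[-nrow(bins)] - 1e-12)) {
    stop("mixed incompatible age bins: bins overlap", call. = FALSE)
  }
  # build the grid directly: selected bins are disjoint but need not be
  # contiguous (e.g. sparse selections)
  grid <- data.frame(
    label = bins$bin_label, lower = bins$lower, upper = bins$upper,
    width = bins$upper - bins$lower, midpoint = (bins$lower + bins$upper) / 2,
    stringsAsFactors = FALSE
  )
  class(grid) <- c("age_grid", "data.frame")

  i <- match(r$bin_label, grid$label)
  counts <- data.frame(
    bin_label = grid$label,
    lower = grid$lower,
    upper = grid$upper,
    deaths = as.numeric(tapply(r$deaths, factor(i, seq_len(nrow(grid))), sum,
                               default = 0)),
    living = as.numeric(tapply(r$living, factor(i, seq_len(nrow(grid))), sum,
                               default = 0)),
    stringsAsFactors = FALSE
  )
  prov <- unique(r[, c("population", "year")])
  prov <- prov[order(prov$population, prov$year), , drop = FALSE]
  rownames(prov) <- NULL
  cause_label <- if (length(unique(r$cause)) == 1L) unique(r$cause) else "ALL"
  structure(
    list(counts = counts, grid = grid, provenance = prov,
         aggregate_name = aggregate_name, cause = cause_label),
    class = "halley_agg"
  )
}

#' Convert a Halley aggregate back to count records
#'
#' The aggregate is expressed in the canonical record schema with the
#' population set to the aggregate name and the year set to the first
#' contributing year (aggregated tables span several years; the year column
#' is kept only to satisfy the schema).
#'
#' @param agg A [halley_aggregate()] result.
#' @return A record data frame.
#' @export
as_count_records <- function(agg) {
  stopifnot(inherits(agg, "halley_agg"))
  data.frame(
    population = agg$aggregate_name,
    year = agg$provenance$year[1L],
    cause = agg$cause,
    bin_label = agg$counts$bin_label,
    lower = agg$counts$lower,
    upper = agg$counts$upper,
    deaths = agg$counts$deaths,
    living = agg$counts$living,
    stringsAsFactors = FALSE
  )
}

#' @export
print.halley_agg <- function(x, ...) {
  cat(sprintf(
    "Halley aggregate '%s' (cause %s): %d bins, %d contributing (population, year) cells\n",
    x$aggregate_name, x$cause, nrow(x$counts), nrow(x$provenance)
  ))
  print.data.frame(x$counts, row.names = FALSE, ...)
  invisible(x)
}
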