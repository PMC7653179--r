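# Age grids -------------------------------------------------------------

# Boundaries of the WHO-style age grid, in years (1 day = 1/365 year):
# four sub-year categories, yearly bins to 5, then 5-year bins to 95.
.who_boundaries <- function() {
  c(0, 1 / 365, 7 / 365, 28 / 365, 1, 2, 3, 4, 5, seq(10, 95, by = 5))
}

.who_labels <- function(boundaries) {
  lab1 <- function(v) {
    if (v == 0) return("0")
    d <- v * 365
    if (v < 1 - 1e-9 && abs(d - round(d)) < 1e-6) {
      sprintf("%dd", as.integer(round(d)))
    } else {
      format(v, trim = TRUE, digits = 10)
    }
  }
  lo <- boundaries[-length(boundaries)]
  hi <- boundaries[-1]
  sprintf("[%s,%s)", vapply(lo, lab1, ""), vapply(hi, lab1, ""))
}

#' Construct an age grid from bin boundaries
#'
#' An age grid is an ordered set of disjoint, contiguous age categories
#' \eqn{[A_i, B_i)} in years.  The representative age of each bin is the
#' arithmetic mean of its endpoints.
#'
#' @param boundaries Strictly increasing numeric vector of bin boundaries in
#'   years; `length(boundaries) - 1` bins are formed.
#' @param labels Optional character labels, one per bin.  Defaults to
#'   `"[lower,upper)"` with sub-year endpoints printed in days.
#' @return A data frame of class `"age_grid"` with columns `label`, `lower`,
#'   `upper`, `width` and `midpoint` (all ages in years).
#' @seealso [standard_age_grid()] for the WHO-style grid.
#' @export
#' @examples
#' age_grid(c(0, 1, 5, 10))
age_grid <- function(boundaries, labels = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) {
    stop("need at least two boundaries to form a bin", call. = FALSE)
  }
  if (any(boundaries < 0)) stop("ages must be non-negative", call. = FALSE)
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- .who_labels(boundaries)
  lower <- boundaries[-length(boundaries)]
  upper <- boundaries[-1]
  if (length(labels) != length(lower)) {
    stop("need one label per bin", call. = FALSE)
  }
  g <- data.frame(
    label = as.character(labels),
    lower = lower,
    upper = upper,
    width = upper - lower,
    midpoint = (lower + upper) / 2,
    stringsAsFactors = FALSE
  )
  class(g) <- c("age_grid", "data.frame")
  g
}

#' The WHO-style standard age grid
#'
#' The grid used by the WHO mortality database: four sub-year categories
#' \eqn{[0, 24 h)}, \eqn{[1, 7 d)}, \eqn{[7, 28 d)}, \eqn{[28, 365 d)},
#' yearly bins \eqn{[1,2)} to \eqn{[4,5)}, and 5-year bins \eqn{[5,10)} up to
#' \eqn{[90,95)}.  All ages are expressed in years with 1 day = 1/365 year.
#'
#' @param min_age,max_age Range to clip the grid to, in years.  Both must be
#'   grid boundaries; `0 <= min_age < max_age <= 95`.
#' @return An [age_grid()] covering `[min_age, max_age)`.
#' @export
#' @examples
#' standard_age_grid(0, 10)   # the nine childhood bins
#' standard_age_grid(0, 1)    # the four infant bins
standard_age_grid <- function(min_age = 0, max_age = 10) {
  b <- .who_boundaries()
  if (!(min_age >= 0 && min_age < max_age && max_age <= 95)) {
    stop("need 0 <= min_age < max_age <= 95", call. = FALSE)
  }
  idx <- function(v, what) {
    i <- which(abs(b - v) < 1e-9)
    if (length(i) != 1L) {
      stop(sprintf(
        "%s = %g is not a grid boundary; legal boundaries (years): %s",
        what, v, paste(signif(b, 6), collapse = ", ")
      ), call. = FALSE)
    }
    i
  }
  i0 <- idx(min_age, "min_age")
  i1 <- idx(max_age, "max_age")
  age_grid(b[i0:i1])
}

# Resolve bin labels against a grid; unknown labels raise a grid error.
.match_bins <- function(labels, grid = standard_age_grid(0, 95)) {
  i <- match(labels, grid$label)
  if (anyNA(i)) {
    bad <- unique(labels[is.na(i)])
    stop(sprintf(
      "unknown age-bin label(s): %s; known labels: %s",
      paste(bad, collapse = ", "), paste(grid$label, collapse = ", ")
    ), call. = FALSE)
  }
  grid[i, , drop = FALSE]
}

# Resolve (lower, upper) bounds in years against a grid, within tolerance.
.match_bins_bounds <- function(lower, upper, grid = standard_age_grid(0, 95)) {
  key <- function(lo, hi) paste(round(lo * 365), round(hi * 365))
  i <- match(key(lower, upper), key(grid$lower, grid$upper))
  if (anyNA(i)) {
    bad <- which(is.na(i))[1L]
    stop(sprintf(
      "age bounds [%g, %g) years do not match a standard grid bin",
      lower[bad], upper[bad]
    ), call. = FALSE)
  }
  grid[i, , drop = FALSE]
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("Age grid: %d bins on [%g, %g) years\n",
              nrow(x), min(x$lower), max(x$upper)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
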