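# Cohort evolution of the age x gender population: within a year, mortality
# is applied first, then net migration, then the age shift, then births --
# the fixed order documented in the methods vignette.

survivor_cells <- function(pop, rates, warn = TRUE) {
  if (!identical(pop$ages, rates$ages)) {
    stop("population and vital rates cover different ages")
  }
  cell <- pop$counts * (1 - rates$mortality) + rates$net_migration
  if (any(cell < 0)) {
    if (warn) {
      warning("net out-migration exceeds survivors in ",
              sum(cell < 0), " cell(s); floored at 0")
    }
    cell[cell < 0] <- 0
  }
  cell
}

#' Advance the population one year
#'
#' Applies mortality, then net migration, then shifts every cohort up one
#' age. The last age is an open-ended absorbing compartment (survivors of
#' the penultimate age plus survivors already in it); age 0 is filled with
#' the year's births.
#'
#' @param pop a [population_grid()].
#' @param rates a [vital_rates()] defined for every (gender, age) in `pop`.
#' @return a `population_grid` for `pop$year + 1`.
#' @export
project_population <- function(pop, rates) {
  stopifnot(inherits(pop, "population_grid"), inherits(rates, "vital_rates"))
  cell <- survivor_cells(pop, rates)
  n <- ncol(cell)
  new <- cell
  if (n > 1L) {
    new[, 2:n] <- cell[, 1:(n - 1L)]
    new[, n] <- cell[, n - 1L] + cell[, n]
  }
  new[, 1L] <- rates$births
  population_grid(new, pop$year + 1L, pop$ages)
}

#' Compare a projected population with a reference, per age band
#'
#' Returns the relative error |model - reference| / reference for each
#' configured age band and gender. Bands whose reference count is zero are
#' flagged and reported as `NA`.
#'
#' @param pop,reference `population_grid`s sharing the same year.
#' @param bands named list of integer age vectors.
#' @return data frame with columns gender, band, model, reference,
#'   rel_error, undefined.
#' @export
population_check <- function(pop, reference,
                             bands = list(`0-14` = 0:14, `15-44` = 15:44,
                                          `45-64` = 45:64, `65+` = 65:85)) {
  if (pop$year != reference$year) stop("grids must share the same year")
  rows <- list()
  for (g in GENDERS) {
    for (b in names(bands)) {
      keep <- as.character(intersect(bands[[b]], pop$ages))
      if (!length(keep)) stop("band ", b, " outside the grid's ages")
      m <- sum(pop$counts[g, keep])
      r <- sum(reference$counts[g, keep])
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, band = b, model = m, reference = r,
        rel_error = if (r > 0) abs(m - r) / r else NA_real_,
        undefined = r == 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$undefined)) {
    warning("zero reference count in band(s): ",
            paste(unique(out$band[out$undefined]), collapse = ", "))
  }
  out
}
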