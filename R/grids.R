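#' @keywords internal
"_PACKAGE"

GENDERS <- c("male", "female")
DEFAULT_AGES <- 0:85

#' Default years-quit classes and widths
#'
#' Former smokers are binned by years since quitting into classes
#' `<1`, `1-2`, `3-5`, `6-10`, `11-15`, `15+` years (widths 1, 2, 3, 5, 5
#' and open-ended). The bins are configurable on every state grid.
#'
#' @export
DEFAULT_QUIT_CLASSES <- c("lt1", "y1_2", "y3_5", "y6_10", "y11_15", "y15p")

#' @rdname DEFAULT_QUIT_CLASSES
#' @export
DEFAULT_QUIT_WIDTHS <- c(1, 2, 3, 5, 5, Inf)
NEVER_SMOKER_MAX_AGE <- 14L  # below 15, everyone is a never smoker

`%||%` <- function(a, b) if (is.null(a)) b else a

state_names <- function(quit_classes) {
  c("never", "daily", "nondaily",
    paste0("fd_", quit_classes), paste0("fn_", quit_classes))
}

#' Age-by-gender population grid
#'
#' Container for person counts per (gender, single age) cell at a calendar
#' year. The last age is open-ended ("85+" in the default configuration).
#'
#' @param counts numeric matrix, 2 rows (male, female) by one column per age.
#' @param year calendar year of the counts.
#' @param ages integer vector of ages; defaults to 0:85 with 85 open-ended.
#'   Shorter vectors are allowed for reduced test configurations.
#' @return object of class `population_grid` with elements `counts`, `year`,
#'   `ages`.
#' @export
population_grid <- function(counts, year, ages = DEFAULT_AGES) {
  counts <- as.matrix(counts)
  ages <- as.integer(ages)
  if (nrow(counts) != 2L || ncol(counts) != length(ages)) {
    stop("counts must be a 2 x ", length(ages), " matrix (gender x age)")
  }
  if (anyNA(counts)) stop("population counts contain NA")
  if (any(counts < 0)) stop("population counts must be non-negative")
  dimnames(counts) <- list(gender = GENDERS, age = as.character(ages))
  structure(list(counts = counts, year = as.integer(year), ages = ages),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat("<population_grid> year", x$year, "-", length(x$ages), "ages, total",
      format(sum(x$counts), big.mark = ","), "\n")
  invisible(x)
}

#' Vital rates driving population evolution
#'
#' @param mortality 2 x n matrix of annual death probabilities per
#'   (gender, age), each in [0, 1].
#' @param net_migration 2 x n matrix of net migrants (persons/year, may be
#'   negative). Defaults to zero.
#' @param births named vector `c(male = , female = )` of newborns per year.
#' @param ages ages the rate columns refer to.
#' @return object of class `vital_rates`.
#' @export
vital_rates <- function(mortality, net_migration = NULL,
                        births = c(male = 0, female = 0),
                        ages = DEFAULT_AGES) {
  ages <- as.integer(ages)
  mortality <- as.matrix(mortality)
  if (nrow(mortality) != 2L || ncol(mortality) != length(ages)) {
    stop("mortality must be a 2 x ", length(ages), " matrix")
  }
  if (anyNA(mortality)) {
    bad <- which(is.na(mortality), arr.ind = TRUE)[1L, ]
    stop(sprintf("mortality undefined for (%s, age %s)",
                 GENDERS[bad[1L]], ages[bad[2L]]))
  }
  if (any(mortality < 0 | mortality > 1)) {
    stop("mortality probabilities must lie in [0, 1]")
  }
  if (is.null(net_migration)) {
    net_migration <- matrix(0, 2L, length(ages))
  }
  net_migration <- as.matrix(net_migration)
  if (anyNA(net_migration) || !all(dim(net_migration) == dim(mortality))) {
    stop("net_migration must be a complete 2 x ", length(ages), " matrix")
  }
  if (anyNA(births) || any(births < 0)) stop("births must be non-negative")
  births <- births[GENDERS]
  if (anyNA(births)) stop("births must be named with 'male' and 'female'")
  dimnames(mortality) <- list(gender = GENDERS, age = as.character(ages))
  dimnames(net_migration) <- dimnames(mortality)
  structure(list(mortality = mortality, net_migration = net_migration,
                 births = births, ages = ages),
            class = "vital_rates")
}

#' Smoking-state occupancy grid
#'
#' Per (gender, age) cell, the fractions of the cohort that are never
#' smokers, current daily smokers, current nondaily smokers, and former
#' daily/nondaily smokers by years-quit class. Fractions in each cell sum
#' to 1.
#'
#' @param frac 3-d array `[gender, age, state]`. State order is
#'   never, daily, nondaily, then former-daily and former-nondaily by quit
#'   class.
#' @param year calendar year.
#' @param ages ages covered.
#' @param quit_classes labels of the years-quit classes.
#' @param quit_widths class widths in years (last may be `Inf`), used for
#'   proportional quit-class aging.
#' @param check validate invariants (sum-to-one, range, under-15 never rule).
#' @return object of class `smoking_state_grid`.
#' @export
smoking_state_grid <- function(frac, year, ages = DEFAULT_AGES,
                               quit_classes = DEFAULT_QUIT_CLASSES,
                               quit_widths = DEFAULT_QUIT_WIDTHS,
                               check = TRUE) {
  ages <- as.integer(ages)
  sn <- state_names(quit_classes)
  if (length(quit_classes) != length(quit_widths)) {
    stop("quit_classes and quit_widths lengths differ")
  }
  if (!is.array(frac) || length(dim(frac)) != 3L ||
      dim(frac)[1L] != 2L || dim(frac)[2L] != length(ages) ||
      dim(frac)[3L] != length(sn)) {
    stop("frac must be a 2 x ", length(ages), " x ", length(sn), " array")
  }
  dimnames(frac) <- list(gender = GENDERS, age = as.character(ages),
                         state = sn)
  grid <- structure(list(frac = frac, year = as.integer(year), ages = ages,
                         quit_classes = quit_classes,
                         quit_widths = quit_widths),
                    class = "smoking_state_grid")
  if (check) validate_state_grid(grid)
  grid
}

validate_state_grid <- function(state, tol = 1e-9) {
  f <- state$frac
  if (any(f < -tol) || any(f > 1 + tol)) {
    stop("state fractions outside [0, 1]")
  }
  sums <- apply(f, c(1L, 2L), sum)
  if (any(abs(sums - 1) > tol)) {
    bad <- which(abs(sums - 1) > tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("state fractions do not sum to 1 for (%s, age %s)",
                 GENDERS[bad[1L]], state$ages[bad[2L]]))
  }
  young <- state$ages <= NEVER_SMOKER_MAX_AGE
  if (any(young)) {
    nv <- f[, young, "never", drop = FALSE]
    if (any(abs(nv - 1) > 1e-12)) {
      stop("cohorts below age 15 must be entirely never smokers")
    }
  }
  invisible(state)
}

#' All-never-smoker state grid
#'
#' @inheritParams smoking_state_grid
#' @export
blank_state <- function(year, ages = DEFAULT_AGES,
                        quit_classes = DEFAULT_QUIT_CLASSES,
                        quit_widths = DEFAULT_QUIT_WIDTHS) {
  sn <- state_names(quit_classes)
  frac <- array(0, dim = c(2L, length(ages), length(sn)))
  frac[, , 1L] <- 1
  smoking_state_grid(frac, year, ages, quit_classes, quit_widths)
}

#' @export
print.smoking_state_grid <- function(x, ...) {
  cat("<smoking_state_grid> year", x$year, "-", length(x$ages), "ages,",
      length(x$quit_classes), "quit classes\n")
  invisible(x)
}

#' Annual transition rates for the smoking-state recursion
#'
#' Initiation is split daily/nondaily and must be zero outside the
#' initiation window; cessation is shared by daily and nondaily smokers;
#' relapse is per years-quit class.
#'
#' @param initiation_daily,initiation_nondaily 2 x n matrices of annual
#'   probabilities that a never smoker initiates, by (gender, age).
#' @param cessation 2 x n matrix of annual quit probabilities.
#' @param relapse numeric vector, one annual relapse probability per quit
#'   class.
#' @param ages ages the columns refer to.
#' @param init_window ages at which initiation may be nonzero (the
#'   transition into age a carries the a-1 to a initiation increment).
#' @return object of class `transition_rates`.
#' @export
transition_rates <- function(initiation_daily, initiation_nondaily,
                             cessation, relapse, ages = DEFAULT_AGES,
                             init_window = 15:28) {
  ages <- as.integer(ages)
  chk <- function(m, what) {
    m <- as.matrix(m)
    if (nrow(m) != 2L || ncol(m) != length(ages)) {
      stop(what, " must be a 2 x ", length(ages), " matrix")
    }
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      stop(what, " probabilities must lie in [0, 1]")
    }
    dimnames(m) <- list(gender = GENDERS, age = as.character(ages))
    m
  }
  initiation_daily <- chk(initiation_daily, "initiation_daily")
  initiation_nondaily <- chk(initiation_nondaily, "initiation_nondaily")
  cessation <- chk(cessation, "cessation")
  outside <- !(ages %in% init_window)
  if (any(initiation_daily[, outside] != 0) ||
      any(initiation_nondaily[, outside] != 0)) {
    stop("initiation must be zero outside ages ",
         min(init_window), "-", max(init_window))
  }
  if (anyNA(relapse) || any(relapse < 0) || any(relapse > 1)) {
    stop("relapse probabilities must lie in [0, 1]")
  }
  structure(list(initiation_daily = initiation_daily,
                 initiation_nondaily = initiation_nondaily,
                 cessation = cessation, relapse = relapse,
                 ages = ages, init_window = as.integer(init_window)),
            class = "transition_rates")
}
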