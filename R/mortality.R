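# Smoking-attributable deaths (SAD). Status-specific death rates are
# decomposed from overall mortality with configurable relative risks: the
# never-smoker rate r_n solves r_n * sum(occupancy_s * RR_s) = overall
# rate, and SAD is the excess-rate formulation pop * occ_s * (r_s - r_n).
# The shipped RR defaults are synthetic, editable placeholders: the source
# publication defers its values to supplementary material.

#' Default relative-risk table (synthetic defaults)
#'
#' Relative risks of death versus never smokers, by gender and broad age
#' band, for daily smokers, nondaily smokers and former smokers by quit
#' class. Former-smoker excess risk decays geometrically toward 1 with
#' years quit. These are plausible editable defaults, not estimates from
#' any specific study.
#'
#' @param quit_classes quit-class labels (default the package's bins).
#' @param decay per-class multipliers on the excess risk for former
#'   smokers, newest class first.
#' @return object of class `rr_table`.
#' @export
default_relative_risks <- function(quit_classes = DEFAULT_QUIT_CLASSES,
                                   decay = c(0.9, 0.7, 0.5, 0.3, 0.15,
                                             0.05)) {
  if (length(decay) != length(quit_classes)) {
    stop("need one decay multiplier per quit class")
  }
  if (is.unsorted(rev(decay))) stop("decay must be non-increasing")
  bands <- data.frame(age_min = c(0, 35, 65), age_max = c(34, 64, 85))
  daily <- rbind(male = c(1.5, 2.5, 2.0), female = c(1.4, 2.2, 1.9))
  nondaily <- rbind(male = c(1.25, 1.75, 1.5), female = c(1.2, 1.6, 1.45))
  structure(list(bands = bands, daily = daily, nondaily = nondaily,
                 decay = decay, quit_classes = quit_classes),
            class = "rr_table")
}

# expand an rr_table to a [gender, age, state] array matching a state grid
expand_rr <- function(rr, ages, quit_classes) {
  stopifnot(identical(rr$quit_classes, quit_classes))
  sn <- state_names(quit_classes)
  out <- array(1, dim = c(2L, length(ages), length(sn)),
               dimnames = list(gender = GENDERS, age = as.character(ages),
                               state = sn))
  band_of <- findInterval(ages, rr$bands$age_min)
  for (g in 1:2) {
    rrd <- rr$daily[g, band_of]
    rrn <- rr$nondaily[g, band_of]
    out[g, , "daily"] <- rrd
    out[g, , "nondaily"] <- rrn
    for (q in seq_along(quit_classes)) {
      out[g, , paste0("fd_", quit_classes[q])] <- 1 + (rrd - 1) * rr$decay[q]
      out[g, , paste0("fn_", quit_classes[q])] <- 1 + (rrn - 1) * rr$decay[q]
    }
  }
  out
}

#' Decompose overall mortality into status-specific death rates
#'
#' Solves for the never-smoker rate such that the occupancy-weighted mean
#' of the status-specific rates reproduces the overall rate exactly.
#'
#' @param overall_mortality overall annual death probability of the cell.
#' @param occupancy named state-occupancy fractions (must sum to > 0).
#' @param rr relative risks for the same states (never = 1).
#' @return named vector of per-status death rates.
#' @export
death_rates_by_status <- function(overall_mortality, occupancy, rr) {
  if (length(occupancy) != length(rr)) {
    stop("occupancy and rr must have the same length")
  }
  tot <- sum(occupancy)
  if (tot <= 0) stop("total occupancy is zero")
  r_n <- overall_mortality * tot / sum(occupancy * rr)
  rates <- r_n * rr
  names(rates) <- names(occupancy)
  rates
}

#' Smoking-attributable deaths of a scenario
#'
#' Excess deaths over the never-smoker rate, per year, gender and smoker
#' type. Former smokers are attributed to the type they quit from.
#'
#' @param result a `scenario_result` (must retain state and population
#'   snapshots, the default).
#' @param vital the [vital_rates()] used in the run.
#' @param rr an `rr_table` (default [default_relative_risks()]).
#' @param years years to include (default: all simulated years).
#' @return data frame: year, gender, type (daily/nondaily), deaths.
#' @export
attributable_deaths <- function(result, vital,
                                rr = default_relative_risks(),
                                years = NULL) {
  yrs <- as.integer(names(result$states))
  if (!is.null(years)) {
    if (!all(years %in% yrs)) stop("requested years outside the run")
    yrs <- intersect(yrs, years)
  }
  st1 <- result$states[[1L]]
  rra <- expand_rr(rr, st1$ages, st1$quit_classes)
  d_states <- c("daily", fd_names(st1))
  n_states <- c("nondaily", fn_names(st1))
  rows <- list()
  for (y in yrs) {
    state <- result$states[[as.character(y)]]
    pop <- result$pops[[as.character(y)]]
    for (g in 1:2) {
      occ <- state$frac[g, , ]
      if (is.null(dim(occ))) occ <- matrix(occ, nrow = 1L,
                                           dimnames = list(NULL,
                                             dimnames(state$frac)[[3L]]))
      rrg <- rra[g, , ]
      if (is.null(dim(rrg))) rrg <- matrix(rrg, nrow = 1L,
                                           dimnames = dimnames(occ))
      m <- vital$mortality[g, ]
      denom <- rowSums(occ * rrg)
      r_n <- m / denom
      excess <- occ * (rrg - 1) * r_n  # per-state excess death probability
      deaths <- excess * pop$counts[g, ]
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, gender = GENDERS[g], type = "daily",
        deaths = sum(deaths[, d_states]), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, gender = GENDERS[g], type = "nondaily",
        deaths = sum(deaths[, n_states]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cumulative difference in smoking-attributable deaths between scenarios
#'
#' @param result_a,result_b `scenario_result`s sharing the same horizon.
#' @inheritParams attributable_deaths
#' @return total deaths in `result_a` minus `result_b`, summed over the
#'   years.
#' @export
sad_difference <- function(result_a, result_b, vital,
                           rr = default_relative_risks(), years = NULL) {
  if (!identical(names(result_a$states), names(result_b$states))) {
    stop("scenarios cover different horizons")
  }
  a <- attributable_deaths(result_a, vital, rr, years)
  b <- attributable_deaths(result_b, vital, rr, years)
  sum(a$deaths) - sum(b$deaths)
}
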