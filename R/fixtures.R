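# Synthetic baseline inputs. No deposited microdata exist for the 2002
# baseline, so every input the simulator needs (population pyramid, vital
# rates, smoking-state occupancy, transition rates, price series, survey
# points) is synthesised from smooth parametric shapes and calibrated so
# the population-weighted ages-15-65 prevalence hits the published 2002
# gender totals exactly. All outputs are pure functions of (spec, seed).

#' Specification of the synthetic baseline
#'
#' Defaults encode the study conditions: 2002 baseline calibrated to the
#' published gender-level prevalences (male daily 21.3%, nondaily 11.9%;
#' female daily 6.9%, nondaily 4.2%), an initiation ramp over ages 15-28, a
#' plateau to age 50 with a late-age decline, a former-smoker stock sized
#' so the implied cessation rate falls in the plausible 2-6%/year range,
#' and relapse declining with years quit.
#'
#' @param seed integer fixing all randomness (only survey synthesis is
#'   stochastic; the baseline itself is deterministic).
#' @param start_year,end_year simulation horizon.
#' @param targets named 2002 prevalence targets (fractions) for
#'   `male_daily`, `male_nondaily`, `female_daily`, `female_nondaily`.
#' @param band calibration/reporting age band.
#' @param ramp_ages ages of the initiation ramp.
#' @param plateau_end last age of the plateau before the late decline.
#' @param decline_to profile multiplier reached at the open-ended age.
#' @param adj65 multiplicative adjustment of the 65+ profile (mimics
#'   re-anchoring of older-age estimates to a second survey).
#' @param former_ratio former-smoker stock as a fraction of current
#'   smokers of the same type.
#' @param quit_dist distribution of former smokers across quit classes
#'   (newest first; must sum to 1).
#' @param relapse annual relapse probability per quit class.
#' @param hundred_cig_screen apply the 100-cigarette lifetime screen to the
#'   baseline definition of current smoking.
#' @param screen_retention fraction of daily/nondaily smokers retained
#'   under the screen (nondaily smokers are much less likely to pass it).
#' @param pop_scale,pop_decay population pyramid: counts per gender at age
#'   a are `pop_scale * exp(-pop_decay * a)`.
#' @param price_start,price_growth,price_growth_years synthetic real price
#'   path parameters (see [synth_price_series()]).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, start_year = 2002L, end_year = 2018L,
                         targets = c(male_daily = 0.213,
                                     male_nondaily = 0.119,
                                     female_daily = 0.069,
                                     female_nondaily = 0.042),
                         band = 15:65,
                         ramp_ages = 15:28, plateau_end = 50L,
                         decline_to = 0.4, adj65 = 1,
                         former_ratio = 0.5,
                         quit_dist = c(0.08, 0.12, 0.15, 0.20, 0.20, 0.25),
                         relapse = c(0.50, 0.15, 0.05, 0.02, 0.01, 0.005),
                         hundred_cig_screen = FALSE,
                         screen_retention = c(daily = 0.9, nondaily = 0.5),
                         pop_scale = 1e6, pop_decay = 0.015,
                         price_start = 30, price_growth = 0.08,
                         price_growth_years = 2003:2011) {
  if (any(targets <= 0) || any(targets >= 1)) {
    stop("prevalence targets must lie in (0, 1)")
  }
  if (abs(sum(quit_dist) - 1) > 1e-9) stop("quit_dist must sum to 1")
  structure(list(seed = as.integer(seed), start_year = as.integer(start_year),
                 end_year = as.integer(end_year), targets = targets,
                 band = band, ramp_ages = ramp_ages,
                 plateau_end = plateau_end, decline_to = decline_to,
                 adj65 = adj65, former_ratio = former_ratio,
                 quit_dist = quit_dist, relapse = relapse,
                 hundred_cig_screen = hundred_cig_screen,
                 screen_retention = screen_retention,
                 pop_scale = pop_scale, pop_decay = pop_decay,
                 price_start = price_start, price_growth = price_growth,
                 price_growth_years = price_growth_years),
            class = "fixture_spec")
}

# smooth age profile: 0 below 15, smooth monotone ramp over ramp_ages,
# plateau at 1, then linear decline to decline_to at the top age
age_profile <- function(spec, ages = DEFAULT_AGES) {
  prof <- numeric(length(ages))
  r0 <- min(spec$ramp_ages) - 1L
  r1 <- max(spec$ramp_ages)
  ramp <- ages >= min(spec$ramp_ages) & ages <= r1
  prof[ramp] <- (1 - cos(pi * (ages[ramp] - r0) / (r1 - r0))) / 2
  prof[ages > r1 & ages <= spec$plateau_end] <- 1
  late <- ages > spec$plateau_end
  top <- max(ages)
  prof[late] <- 1 - (1 - spec$decline_to) *
    (ages[late] - spec$plateau_end) / (top - spec$plateau_end)
  prof[ages >= 65] <- prof[ages >= 65] * spec$adj65
  prof
}

#' Synthesise the complete 2002 baseline
#'
#' Builds the population grid, vital rates, smoking-state grid and
#' transition rates. The smoking profiles are scaled after shaping so the
#' population-weighted band prevalence matches the spec targets to within
#' 1e-6; initiation is derived from the profile via [derive_initiation()]
#' and cessation from the former-smoker stock via
#' [derive_cessation_from_state()].
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `pop`, `state`, `rates`, `vital`, `spec`.
#' @export
synth_baseline <- function(spec = fixture_spec()) {
  ages <- DEFAULT_AGES
  n <- length(ages)

  counts <- rbind(male = spec$pop_scale * exp(-spec$pop_decay * ages),
                  female = spec$pop_scale * exp(-spec$pop_decay * ages))
  pop <- population_grid(counts, spec$start_year, ages)

  # mortality: infant component + background + late-age exponential rise
  base_m <- 0.01 * exp(-ages / 2) + 3e-4 + 8e-5 * exp(0.085 * ages)
  mort <- rbind(male = pmin(0.95, base_m * 1.15),
                female = pmin(0.95, base_m))
  vital <- vital_rates(mort, matrix(0, 2L, n),
                       births = c(male = unname(counts[1L, 1L]),
                                  female = unname(counts[2L, 1L])),
                       ages = ages)

  prof <- age_profile(spec, ages)
  band_idx <- as.character(intersect(spec$band, ages))
  qd <- spec$quit_dist
  nq <- length(DEFAULT_QUIT_CLASSES)
  sn <- state_names(DEFAULT_QUIT_CLASSES)
  frac <- array(0, dim = c(2L, n, length(sn)),
                dimnames = list(gender = GENDERS,
                                age = as.character(ages), state = sn))
  for (g in GENDERS) {
    w <- pop$counts[g, band_idx]
    wmean <- sum(prof[ages %in% spec$band] * w) / sum(w)
    for (ty in c("daily", "nondaily")) {
      target <- spec$targets[[paste0(g, "_", ty)]]
      cur <- target / wmean * prof
      if (spec$hundred_cig_screen) {
        cur <- cur * spec$screen_retention[[ty]]
      }
      frac[g, , ty] <- cur
      former <- spec$former_ratio * cur
      pre <- if (ty == "daily") "fd_" else "fn_"
      for (q in seq_len(nq)) {
        frac[g, , paste0(pre, DEFAULT_QUIT_CLASSES[q])] <- former * qd[q]
      }
    }
  }
  occupied <- apply(frac[, , -1L, drop = FALSE], c(1L, 2L), sum)
  if (any(occupied >= 1)) {
    stop("infeasible targets: smoking states exceed the whole cohort")
  }
  frac[, , "never"] <- 1 - occupied
  state <- smoking_state_grid(frac, spec$start_year, ages)

  init <- derive_initiation(state)
  cess <- derive_cessation_from_state(state)
  rates <- transition_rates(init$initiation_daily, init$initiation_nondaily,
                            cess, spec$relapse, ages)

  list(pop = pop, state = state, rates = rates, vital = vital, spec = spec)
}

#' Synthetic annual real cigarette price series
#'
#' Deterministic path: constant growth during the configured growth years,
#' flat otherwise.
#'
#' @param spec a [fixture_spec()].
#' @return year-named numeric vector covering the spec horizon.
#' @export
synth_price_series <- function(spec = fixture_spec()) {
  if (spec$price_start <= 0) stop("start price must be positive")
  years <- seq(spec$start_year, spec$end_year)
  p <- numeric(length(years))
  p[1L] <- spec$price_start
  for (i in seq_along(years)[-1L]) {
    g <- if (years[i] %in% spec$price_growth_years) spec$price_growth else 0
    p[i] <- p[i - 1L] * (1 + g)
  }
  stats::setNames(p, as.character(years))
}

#' Synthetic survey point estimates around a model trajectory
#'
#' For testing the survey-validation machinery: draws noisy point
#' estimates around the model's band prevalence with binomial-style 95%
#' confidence intervals.
#'
#' @param truth a `scenario_result` supplying the underlying trajectory.
#' @param years survey years (must be simulated years).
#' @param noise_sd standard deviation of the additive noise on the
#'   prevalence scale (0 = estimates equal the model exactly).
#' @param n_eff effective sample size per stratum for the CI half-width.
#' @param seed RNG seed fixing the draws.
#' @return data frame: year, gender, type, estimate, lower, upper, survey.
#' @export
synth_surveys <- function(truth, years, noise_sd = 0.01, n_eff = 4000,
                          seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (y in years) {
    for (g in GENDERS) {
      for (ty in c("daily", "nondaily")) {
        p <- get_prevalence(truth, y, g, ty)
        est <- max(1e-6, p + stats::rnorm(1L, 0, noise_sd))
        half <- 1.96 * sqrt(est * (1 - est) / n_eff)
        rows[[length(rows) + 1L]] <- data.frame(
          year = y, gender = g, type = ty, estimate = est,
          lower = max(0, est - half), upper = min(1, est + half),
          survey = paste0("synthetic_", y), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
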