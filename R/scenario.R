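# Scenario orchestration: the annual loop (demographics step, policy
# modifiers, smoking-state step, summaries), status-quo vs counterfactual
# comparison, per-policy attribution and survey validation.

#' Bundle everything a simulation run needs
#'
#' @param baseline list with elements `pop` ([population_grid()]), `state`
#'   ([smoking_state_grid()]), `rates` ([transition_rates()]) and `vital`
#'   ([vital_rates()]), e.g. from [synth_baseline()] or
#'   [read_baseline_csv()].
#' @param timeline a [policy_timeline()].
#' @param end_year final simulated year.
#' @param effect_table an `effect_table` (defaults to the packaged one).
#' @param band reporting age band (default 15:65).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(baseline, timeline, end_year,
                            effect_table = default_effect_table(),
                            band = 15:65) {
  stopifnot(inherits(baseline$pop, "population_grid"),
            inherits(baseline$state, "smoking_state_grid"),
            inherits(baseline$rates, "transition_rates"),
            inherits(baseline$vital, "vital_rates"),
            inherits(timeline, "policy_timeline"))
  if (end_year < baseline$pop$year) {
    stop("horizon ends before the baseline year")
  }
  structure(list(baseline = baseline, timeline = timeline,
                 end_year = as.integer(end_year),
                 effect_table = effect_table, band = band),
            class = "scenario_config")
}

#' Run a full simulation
#'
#' Deterministic annual loop from the baseline year to the configured
#' horizon: cohort aging of population and state fractions, policy
#' modifiers for the year, then the five-stage smoking-state step.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_result` with elements `prevalence`
#'   (data frame: year, gender, type, band, value), `states`, `pops`
#'   (per-year snapshots) and `meta`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  pop <- config$baseline$pop
  state <- config$baseline$state
  rates <- config$baseline$rates
  vital <- config$baseline$vital
  timeline <- config$timeline
  table <- config$effect_table
  band <- config$band
  years <- seq(pop$year, config$end_year)

  states <- vector("list", length(years))
  pops <- vector("list", length(years))
  names(states) <- names(pops) <- as.character(years)
  prev_rows <- vector("list", length(years))

  record <- function(i, state, pop) {
    states[[i]] <<- state
    pops[[i]] <<- pop
    s <- prevalence_summary(state, pop, band)
    s$year <- years[i]
    s$band <- paste0(min(band), "-", max(band))
    prev_rows[[i]] <<- s[, c("year", "gender", "type", "band", "prevalence")]
  }
  record(1L, state, pop)

  if (length(years) > 1L) {
    for (i in 2:length(years)) {
      y <- years[i]
      mods <- build_modifiers(timeline, table, y, state$ages)
      state <- age_states(state, pop, vital)
      state <- step_states(state, rates, mods)
      pop <- project_population(pop, vital)
      record(i, state, pop)
    }
  }

  structure(list(prevalence = do.call(rbind, prev_rows),
                 states = states, pops = pops,
                 meta = list(start_year = years[1L],
                             end_year = config$end_year,
                             band = band,
                             timeline = timeline$name,
                             nondaily_scale = timeline$nondaily_scale)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$meta$timeline, "-",
      x$meta$start_year, "to", x$meta$end_year, "\n")
  last <- x$prevalence[x$prevalence$year == x$meta$end_year, ]
  last$prevalence <- sprintf("%.1f%%", 100 * last$prevalence)
  print(last[, c("gender", "type", "prevalence")], row.names = FALSE)
  invisible(x)
}

#' Look up a band prevalence in a result
#'
#' @param result a `scenario_result`.
#' @param year,gender,type stratum selectors.
#' @return prevalence as a fraction.
#' @export
get_prevalence <- function(result, year, gender, type) {
  p <- result$prevalence
  hit <- p$year == year & p$gender == gender & p$type == type
  if (!any(hit)) {
    stop(sprintf("no prevalence recorded for %s %s in %d",
                 gender, type, year))
  }
  p$prevalence[hit][1L]
}

#' Relative difference between two scenarios
#'
#' The policy impact measure: `100 * (p_sq - p_cf) / p_cf` percent, for a
#' given year and stratum. Numeric inputs are also accepted directly.
#'
#' @param status_quo,counterfactual `scenario_result`s (or plain prevalence
#'   numbers).
#' @param year,gender,type stratum selectors (ignored for numeric inputs).
#' @return relative difference in percent; `NA` with a warning when the
#'   counterfactual prevalence is zero.
#' @export
relative_difference <- function(status_quo, counterfactual, year = NULL,
                                gender = "male", type = "daily") {
  p_sq <- if (is.numeric(status_quo)) status_quo else {
    get_prevalence(status_quo, year, gender, type)
  }
  p_cf <- if (is.numeric(counterfactual)) counterfactual else {
    get_prevalence(counterfactual, year, gender, type)
  }
  if (length(p_cf) == 1L && p_cf == 0) {
    warning("counterfactual prevalence is zero; relative difference ",
            "undefined")
    return(NA_real_)
  }
  100 * (p_sq - p_cf) / p_cf
}

#' Relative differences for every stratum in one year
#'
#' @inheritParams relative_difference
#' @return data frame: gender, type, status_quo, counterfactual,
#'   relative_difference (percent).
#' @export
relative_difference_table <- function(status_quo, counterfactual, year) {
  rows <- list()
  for (g in GENDERS) {
    for (ty in c("daily", "nondaily")) {
      p1 <- get_prevalence(status_quo, year, g, ty)
      p0 <- get_prevalence(counterfactual, year, g, ty)
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, type = ty, status_quo = p1, counterfactual = p0,
        relative_difference = if (p0 > 0) 100 * (p1 - p0) / p0 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Attribute the combined reduction to individual policies
#'
#' Because policy effects combine non-additively, each policy's role is
#' measured relative to the summed effects of all single-policy runs:
#' `share_i = reduction_i / sum_j reduction_j`.
#'
#' @param per_policy named list of single-policy `scenario_result`s (each
#'   varying exactly one family from baseline levels).
#' @param counterfactual the all-baseline-levels `scenario_result`.
#' @param year evaluation year.
#' @param gender,type stratum.
#' @return data frame: policy, prevalence, reduction, share. Shares sum to
#'   1; all-zero reductions yield `NA` shares with a warning.
#' @export
attribute_policies <- function(per_policy, counterfactual, year,
                               gender = "male", type = "daily") {
  p_cf <- get_prevalence(counterfactual, year, gender, type)
  red <- unname(vapply(per_policy, function(r) {
    p_cf - get_prevalence(r, year, gender, type)
  }, numeric(1L)))
  tot <- sum(red)
  share <- if (tot == 0) {
    warning("all policy reductions are zero; shares undefined")
    rep(NA_real_, length(red))
  } else {
    red / tot
  }
  data.frame(policy = names(per_policy),
             prevalence = p_cf - red,
             reduction = red, share = share,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare model prevalence with survey point estimates
#'
#' @param result a `scenario_result`.
#' @param surveys data frame with columns year, gender, type, estimate,
#'   lower, upper and (optionally) survey. Estimates are fractions on the
#'   result's reporting band.
#' @return data frame adding `model`, `rel_error` = (model - estimate) /
#'   estimate, and `ci_flag` in {"below CI", "within CI", "above CI"}
#'   (closed intervals). Points outside the simulated years are skipped
#'   with a warning.
#' @export
validate_against_surveys <- function(result, surveys) {
  stopifnot(all(c("year", "gender", "type", "estimate", "lower", "upper")
                %in% names(surveys)))
  if (any(surveys$lower > surveys$estimate |
          surveys$estimate > surveys$upper)) {
    stop("survey estimates must lie inside their confidence bounds")
  }
  keep <- logical(nrow(surveys))
  model <- rel_error <- numeric(nrow(surveys))
  flag <- character(nrow(surveys))
  yrs <- unique(result$prevalence$year)
  for (i in seq_len(nrow(surveys))) {
    s <- surveys[i, ]
    if (!(s$year %in% yrs)) next
    keep[i] <- TRUE
    m <- get_prevalence(result, s$year, s$gender, s$type)
    model[i] <- m
    rel_error[i] <- if (s$estimate != 0) (m - s$estimate) / s$estimate else
      NA_real_
    flag[i] <- if (m < s$lower) "below CI" else if (m > s$upper)
      "above CI" else "within CI"
  }
  if (any(!keep)) {
    warning(sum(!keep), " survey point(s) outside the simulated years; ",
            "skipped")
  }
  out <- surveys[keep, , drop = FALSE]
  out$model <- model[keep]
  out$rel_error <- rel_error[keep]
  out$ci_flag <- flag[keep]
  out
}

#' Run the status quo, counterfactual and single-policy scenarios
#'
#' @param config a [scenario_config()] holding the full (status-quo)
#'   timeline.
#' @param families policy families for single-policy runs; defaults to all
#'   families in the timeline plus price.
#' @return list with `status_quo`, `counterfactual` and `per_policy` (a
#'   named list of `scenario_result`s).
#' @export
run_policy_comparison <- function(config, families = NULL) {
  tl <- config$timeline
  if (is.null(families)) {
    families <- names(tl$policies)
    if (!is.null(tl$price)) families <- c("price", families)
  }
  swap <- function(new_tl) {
    cfg <- config
    cfg$timeline <- new_tl
    cfg
  }
  status_quo <- run_scenario(config)
  counterfactual <- run_scenario(swap(freeze_timeline(tl)))
  per_policy <- lapply(families, function(f) {
    run_scenario(swap(isolate_policy(tl, f)))
  })
  names(per_policy) <- families
  list(status_quo = status_quo, counterfactual = counterfactual,
       per_policy = per_policy)
}
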