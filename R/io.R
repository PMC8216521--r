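# Plain-CSV interfaces for the baseline inputs, so the simulator can be
# driven from files prepared outside R and fixtures can round-trip.

#' Write a baseline bundle to CSV files
#'
#' Writes population.csv, vital_rates.csv, births.csv, smoking_state.csv,
#' transition_rates.csv, relapse.csv and meta.csv into `dir`.
#'
#' @param baseline list as returned by [synth_baseline()] (elements `pop`,
#'   `state`, `rates`, `vital`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_baseline_csv <- function(baseline, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- baseline$pop
  state <- baseline$state
  rates <- baseline$rates
  vital <- baseline$vital
  ages <- pop$ages
  grid <- expand.grid(gender = GENDERS, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  pv <- function(m) m[cbind(match(grid$gender, GENDERS),
                            match(grid$age, ages))]
  utils::write.csv(cbind(grid, count = pv(pop$counts)),
                   file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(cbind(grid, mortality = pv(vital$mortality),
                         net_migration = pv(vital$net_migration)),
                   file.path(dir, "vital_rates.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gender = GENDERS, births = vital$births),
                   file.path(dir, "births.csv"), row.names = FALSE)

  sn <- dimnames(state$frac)[[3L]]
  st <- expand.grid(gender = GENDERS, age = ages, state = sn,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st$value <- state$frac[cbind(match(st$gender, GENDERS),
                               match(st$age, ages),
                               match(st$state, sn))]
  utils::write.csv(st, file.path(dir, "smoking_state.csv"),
                   row.names = FALSE)

  utils::write.csv(cbind(grid,
                         initiation_daily = pv(rates$initiation_daily),
                         initiation_nondaily = pv(rates$initiation_nondaily),
                         cessation = pv(rates$cessation)),
                   file.path(dir, "transition_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(quit_class = state$quit_classes,
                              width = state$quit_widths,
                              relapse = rates$relapse),
                   file.path(dir, "relapse.csv"), row.names = FALSE)
  utils::write.csv(data.frame(key = c("year", "init_window_min",
                                      "init_window_max"),
                              value = c(pop$year, min(rates$init_window),
                                        max(rates$init_window))),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a baseline bundle from CSV files
#'
#' Inverse of [write_baseline_csv()].
#'
#' @param dir directory holding the CSV files.
#' @return list with elements `pop`, `state`, `rates`, `vital`.
#' @export
read_baseline_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  meta <- rd("meta.csv")
  mval <- function(k) as.numeric(meta$value[meta$key == k])
  year <- as.integer(mval("year"))

  popdf <- rd("population.csv")
  ages <- sort(unique(popdf$age))
  tomat <- function(df, col) {
    m <- matrix(NA_real_, 2L, length(ages))
    m[cbind(match(df$gender, GENDERS), match(df$age, ages))] <- df[[col]]
    m
  }
  pop <- population_grid(tomat(popdf, "count"), year, ages)

  vdf <- rd("vital_rates.csv")
  bdf <- rd("births.csv")
  vital <- vital_rates(tomat(vdf, "mortality"), tomat(vdf, "net_migration"),
                       births = stats::setNames(bdf$births, bdf$gender),
                       ages = ages)

  rel <- rd("relapse.csv")
  sn <- state_names(rel$quit_class)
  sdf <- rd("smoking_state.csv")
  frac <- array(NA_real_, dim = c(2L, length(ages), length(sn)))
  frac[cbind(match(sdf$gender, GENDERS), match(sdf$age, ages),
             match(sdf$state, sn))] <- sdf$value
  state <- smoking_state_grid(frac, year, ages, rel$quit_class, rel$width)

  tdf <- rd("transition_rates.csv")
  rates <- transition_rates(tomat(tdf, "initiation_daily"),
                            tomat(tdf, "initiation_nondaily"),
                            tomat(tdf, "cessation"), rel$relapse, ages,
                            init_window = seq(mval("init_window_min"),
                                              mval("init_window_max")))
  list(pop = pop, state = state, rates = rates, vital = vital)
}
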