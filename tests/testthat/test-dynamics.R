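test_that("zero rates and no shock leave the smoking states unchanged", {
  st <- make_toy_state()
  rates <- make_toy_rates(cessation = 0, relapse = c(0, 0))
  out <- step_states(st, rates)
  # never/daily/nondaily untouched; former mass per type conserved even
  # though the quit-class clock still advances
  for (s in c("never", "daily", "nondaily")) {
    expect_equal(out$frac[, , s], st$frac[, , s], tolerance = 1e-15)
  }
  expect_equal(out$frac[, , "fd_q1"] + out$frac[, , "fd_q2"],
               st$frac[, , "fd_q1"] + st$frac[, , "fd_q2"],
               tolerance = 1e-15)

  # with all former mass already in the terminal class the step is the
  # exact identity
  frac <- st$frac
  frac[, , "fd_q2"] <- frac[, , "fd_q2"] + frac[, , "fd_q1"]
  frac[, , "fn_q2"] <- frac[, , "fn_q2"] + frac[, , "fn_q1"]
  frac[, , "fd_q1"] <- 0
  frac[, , "fn_q1"] <- 0
  st2 <- smoking_state_grid(frac, st$year, st$ages, toy_quit_classes,
                            toy_quit_widths)
  out2 <- step_states(st2, rates)
  expect_equal(out2$frac, st2$frac, tolerance = 1e-15)
})

test_that("cessation moves smokers into the recent-quit compartment", {
  ages <- c(30, 31, 32)
  sn <- c("never", "daily", "nondaily", "fd_q1", "fd_q2", "fn_q1", "fn_q2")
  frac <- array(0, dim = c(2, 3, 7))
  frac[, , 1] <- 0.8
  frac[, , 2] <- 0.2
  st <- smoking_state_grid(frac, 2002, ages, toy_quit_classes,
                           toy_quit_widths)
  rates <- make_toy_rates(cessation = 0.05, relapse = c(0, 0))
  out <- step_states(st, rates)
  expect_equal(unname(out$frac[1, 1, "daily"]), 0.19)
  expect_equal(unname(out$frac[1, 1, "fd_q1"]), 0.01)
  expect_equal(unname(out$frac[1, 1, "never"]), 0.8)
})

test_that("quit-class aging flows proportionally to class width", {
  ages <- c(30, 31, 32)
  frac <- array(0, dim = c(2, 3, 7))
  frac[, , 1] <- 0.9
  frac[, , 4] <- 0.06  # fd_q1, width 1: all advances
  frac[, , 5] <- 0.04  # fd_q2, open-ended: absorbs
  st <- smoking_state_grid(frac, 2002, ages, toy_quit_classes,
                           toy_quit_widths)
  rates <- make_toy_rates(cessation = 0, relapse = c(0, 0))
  out <- step_states(st, rates)
  expect_equal(unname(out$frac[1, 1, "fd_q1"]), 0)
  expect_equal(unname(out$frac[1, 1, "fd_q2"]), 0.10)
})

test_that("occupancy is conserved under random rates and modifiers", {
  set.seed(7)
  for (rep in 1:20) {
    ages <- c(30, 31, 32)
    frac <- array(0, dim = c(2, 3, 7))
    cur <- matrix(runif(12, 0, 0.15), 2, 6)  # daily..fn_q2 per cell
    for (g in 1:2) for (i in 1:3) {
      frac[g, i, 2:7] <- runif(6, 0, 0.12)
      frac[g, i, 1] <- 1 - sum(frac[g, i, 2:7])
    }
    st <- smoking_state_grid(frac, 2002, ages, toy_quit_classes,
                             toy_quit_widths)
    rates <- make_toy_rates(cessation = runif(1, 0, 0.3),
                            relapse = runif(2, 0, 0.5),
                            init_daily = runif(1, 0, 0.1),
                            init_nondaily = runif(1, 0, 0.1))
    mods <- make_toy_modifiers(shock_d = runif(1, 0, 0.1),
                               shock_n = runif(1, 0, 0.1),
                               im = runif(1, 0, 1.5),
                               cm = runif(1, 0, 1.5))
    out <- step_states(st, rates, mods)
    sums <- apply(out$frac, c(1, 2), sum)
    expect_true(all(abs(sums - 1) <= 1e-9))
  }
})

test_that("five steps match the brute-force scalar recurrence to 1e-12", {
  st <- make_toy_state()
  rates <- make_toy_rates(cessation = 0.07, relapse = c(0.25, 0.04),
                          init_daily = 0.02, init_nondaily = 0.015)
  mods <- make_toy_modifiers(shock_d = 0.03, shock_n = 0.02,
                             im = 0.9, cm = 1.2)
  cells <- state_to_cells(st)
  cur <- st
  for (k in 1:5) {
    cur <- step_states(cur, rates, mods)
    for (nm in names(cells)) {
      g <- as.integer(substr(nm, 1, 1))
      i <- as.integer(substr(nm, 3, 3))
      cells[[nm]] <- oracle_step_cell(
        cells[[nm]], toy_quit_widths, 0.02, 0.015, 0.07, c(0.25, 0.04),
        0.9, 0.9, 1.2, 1.2, 0.03, 0.02)
    }
  }
  expect_equal(cur$frac, cells_to_array(cells, st), tolerance = 1e-12)
})

test_that("initiation rates follow consecutive-age prevalence increments", {
  # daily 10% at 19 and 12% at 20 with an 80% never pool at 19
  ages <- 13:28
  sn_len <- 3 + 2 * length(DEFAULT_QUIT_CLASSES)
  frac <- array(0, dim = c(2, length(ages), sn_len))
  daily <- ifelse(ages >= 20, 0.12, ifelse(ages >= 19, 0.10, 0))
  nond <- ifelse(ages >= 19, 0.10, 0)
  frac[, , 2] <- rep(daily, each = 2)
  frac[, , 3] <- rep(nond, each = 2)
  frac[, , 1] <- 1 - frac[, , 2] - frac[, , 3]
  st <- smoking_state_grid(frac, 2002, ages, check = FALSE)
  init <- derive_initiation(st, window = 15:28)
  expect_equal(unname(init$initiation_daily[1, "20"]), 0.02 / 0.8)
  expect_equal(unname(init$initiation_daily[1, "21"]), 0)
})

test_that("a flat prevalence profile yields no initiation, with a warning", {
  ages <- 13:28
  sn_len <- 3 + 2 * length(DEFAULT_QUIT_CLASSES)
  frac <- array(0, dim = c(2, length(ages), sn_len))
  frac[, , 2] <- 0.15
  frac[, , 1] <- 0.85
  st <- smoking_state_grid(frac, 2002, ages, check = FALSE)
  expect_warning(init <- derive_initiation(st, window = 15:28),
                 "no net initiation")
  expect_true(all(init$initiation_daily == 0))
})

test_that("derived initiation reproduces the baseline profile forward", {
  # no former smokers, no cessation: running the cohort forward from age
  # 14 with the derived rates must retrace the baseline curve exactly
  spec <- fixture_spec(former_ratio = 0)
  b <- synth_baseline(spec)
  pop <- b$pop
  state <- blank_state(b$pop$year)
  vital <- vital_rates(matrix(0, 2, 86), births = c(male = 1, female = 1))
  rates <- transition_rates(b$rates$initiation_daily,
                            b$rates$initiation_nondaily,
                            matrix(0, 2, 86), rep(0, 6))
  for (k in 1:40) {
    state <- step_states(age_states(state, pop, vital), rates)
    pop <- project_population(pop, vital)
  }
  for (a in as.character(15:28)) {
    expect_equal(state$frac[, a, "daily"], b$state$frac[, a, "daily"],
                 tolerance = 1e-9)
    expect_equal(state$frac[, a, "nondaily"],
                 b$state$frac[, a, "nondaily"], tolerance = 1e-9)
  }
})

test_that("cessation rate is quitters over smokers at risk", {
  expect_equal(derive_cessation(95, 5), 0.05)
  expect_equal(derive_cessation(190, 10), 0.05)  # scale invariance
  expect_equal(suppressWarnings(derive_cessation(0, 0)), 0)
  expect_warning(derive_cessation(0, 0), "zero denominator")
  expect_equal(derive_cessation(100, 0), 0)
})

test_that("prevalence summaries are population-weighted means", {
  ages <- c(40, 41)
  frac <- array(0, dim = c(2, 2, 15))
  frac[, 1, 2] <- 0.10
  frac[, 2, 2] <- 0.20
  frac[, , 1] <- 1 - frac[, , 2]
  st <- smoking_state_grid(frac, 2002, ages, check = FALSE)

  eq <- population_grid(matrix(100, 2, 2), 2002, ages)
  expect_equal(prevalence_summary(st, eq, band = 40:41,
                                  types = "daily")$prevalence,
               c(0.15, 0.15))

  w31 <- population_grid(matrix(c(300, 300, 100, 100), 2, 2), 2002, ages)
  expect_equal(prevalence_summary(st, w31, band = 40:41,
                                  types = "daily")$prevalence,
               c(0.125, 0.125))

  uni <- prevalence_summary(st, eq, band = 40, types = "daily")
  expect_equal(uni$prevalence, c(0.10, 0.10))
  expect_error(prevalence_summary(st, eq, band = 70:80), "empty age band")
})

test_that("the never fraction of a cohort never increases with age", {
  b <- shared_baseline()
  cfg <- scenario_config(b, freeze_timeline(mexico_timeline()), 2018)
  res <- run_scenario(cfg)
  yrs <- as.character(2002:2018)
  for (g in 1:2) {
    # follow the cohort aged 14 in 2002 (never = 1 at the start)
    nv <- vapply(seq_along(yrs), function(i) {
      res$states[[yrs[i]]]$frac[g, as.character(14 + i - 1), "never"]
    }, numeric(1))
    expect_true(all(diff(nv) <= 1e-12))
  }
})

test_that("without relapse or initiation, prevalence decays at least
           geometrically at the cessation floor", {
  st <- make_toy_state()
  q <- 0.04
  rates <- make_toy_rates(cessation = q, relapse = c(0, 0))
  cur <- st
  for (k in 1:10) cur <- step_states(cur, rates)
  expect_true(all(cur$frac[, , "daily"] <=
                  st$frac[, , "daily"] * (1 - q)^10 + 1e-12))
})

test_that("raising the cessation multiplier never raises later prevalence", {
  st <- make_toy_state()
  rates <- make_toy_rates(cessation = 0.05, relapse = c(0.2, 0.05),
                          init_daily = 0.01, init_nondaily = 0.01)
  lo <- st
  hi <- st
  for (k in 1:10) {
    lo <- step_states(lo, rates, make_toy_modifiers(cm = 1))
    hi <- step_states(hi, rates, make_toy_modifiers(cm = 1.4))
    expect_true(all(hi$frac[, , "daily"] <= lo$frac[, , "daily"] + 1e-12))
    expect_true(all(hi$frac[, , "nondaily"] <=
                    lo$frac[, , "nondaily"] + 1e-12))
  }
})

test_that("invalid modifiers and misconfigured flows are rejected", {
  st <- make_toy_state()
  rates <- make_toy_rates()
  bad <- make_toy_modifiers(im = -0.5)
  expect_error(step_states(st, rates, bad), "non-negative")
  huge <- make_toy_modifiers(cm = 1e3)
  expect_error(step_states(st, rates, huge), "exceeds current smokers")
})
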