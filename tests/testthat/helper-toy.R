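# Small toy configurations and an independent brute-force scalar oracle
# for the smoking-state recursion. The oracle is written with explicit
# per-cell loops and named scalars, deliberately sharing no code with the
# package's vectorised implementation.

toy_quit_classes <- c("q1", "q2")
toy_quit_widths <- c(1, Inf)

# a 3-age, 2-quit-class state grid with hand-set occupancy
make_toy_state <- function(year = 2002, ages = c(30, 31, 32)) {
  sn <- c("never", "daily", "nondaily", "fd_q1", "fd_q2", "fn_q1", "fn_q2")
  frac <- array(0, dim = c(2, length(ages), length(sn)))
  # male
  frac[1, , ] <- rbind(c(0.50, 0.25, 0.10, 0.04, 0.06, 0.02, 0.03),
                       c(0.45, 0.28, 0.12, 0.03, 0.07, 0.02, 0.03),
                       c(0.40, 0.30, 0.10, 0.05, 0.10, 0.02, 0.03))
  # female
  frac[2, , ] <- rbind(c(0.70, 0.12, 0.06, 0.03, 0.05, 0.02, 0.02),
                       c(0.65, 0.15, 0.07, 0.03, 0.06, 0.02, 0.02),
                       c(0.60, 0.18, 0.08, 0.04, 0.06, 0.02, 0.02))
  smoking_state_grid(frac, year, ages, toy_quit_classes, toy_quit_widths)
}

make_toy_rates <- function(ages = c(30, 31, 32),
                           cessation = 0.05,
                           relapse = c(0.2, 0.05),
                           init_daily = 0, init_nondaily = 0) {
  m <- function(v) matrix(v, 2, length(ages))
  transition_rates(m(init_daily), m(init_nondaily), m(cessation), relapse,
                   ages = ages, init_window = ages)
}

make_toy_modifiers <- function(ages = c(30, 31, 32), shock_d = 0,
                               shock_n = 0, im = 1, cm = 1) {
  mods <- identity_modifiers(ages)
  mods$shock[, , "daily"] <- shock_d
  mods$shock[, , "nondaily"] <- shock_n
  mods$init_mult[, , ] <- im
  mods$cess_mult[, , ] <- cm
  mods
}

# ---- brute-force scalar recurrence -------------------------------------

# one cell, one year of transitions; cell is a named list of scalars
oracle_step_cell <- function(cell, widths, init_d, init_n, cess, relapse,
                             im_d, im_n, cm_d, cm_n, s_d, s_n) {
  nq <- length(widths)
  fd <- cell$fd
  fn <- cell$fn
  # 1. quit-class aging
  out_d <- numeric(nq)
  out_n <- numeric(nq)
  for (q in seq_len(nq)) {
    if (is.finite(widths[q])) {
      out_d[q] <- fd[q] / widths[q]
      out_n[q] <- fn[q] / widths[q]
    }
  }
  for (q in seq_len(nq)) {
    fd[q] <- fd[q] - out_d[q] + if (q > 1) out_d[q - 1] else 0
    fn[q] <- fn[q] - out_n[q] + if (q > 1) out_n[q - 1] else 0
  }
  # 2. initiation
  inc_d <- cell$never * init_d * im_d
  inc_n <- cell$never * init_n * im_n
  never <- cell$never - inc_d - inc_n
  daily <- cell$daily + inc_d
  nond <- cell$nondaily + inc_n
  # 3. cessation
  quit_d <- daily * cess * cm_d
  quit_n <- nond * cess * cm_n
  daily <- daily - quit_d
  nond <- nond - quit_n
  fd[1] <- fd[1] + quit_d
  fn[1] <- fn[1] + quit_n
  # 4. relapse
  for (q in seq_len(nq)) {
    r_d <- fd[q] * relapse[q]
    r_n <- fn[q] * relapse[q]
    fd[q] <- fd[q] - r_d
    fn[q] <- fn[q] - r_n
    daily <- daily + r_d
    nond <- nond + r_n
  }
  # 5. prevalence shock
  mv_d <- daily * s_d
  mv_n <- nond * s_n
  daily <- daily - mv_d
  nond <- nond - mv_n
  fd[1] <- fd[1] + mv_d
  fn[1] <- fn[1] + mv_n
  list(never = never, daily = daily, nondaily = nond, fd = fd, fn = fn)
}

state_to_cells <- function(state) {
  nq <- length(state$quit_classes)
  cells <- list()
  for (g in 1:2) {
    for (i in seq_along(state$ages)) {
      f <- state$frac[g, i, ]
      cells[[paste(g, i)]] <- list(
        never = unname(f["never"]), daily = unname(f["daily"]),
        nondaily = unname(f["nondaily"]),
        fd = unname(f[3 + seq_len(nq)]),
        fn = unname(f[3 + nq + seq_len(nq)]))
    }
  }
  cells
}

cells_to_array <- function(cells, state) {
  out <- state$frac
  nq <- length(state$quit_classes)
  for (g in 1:2) {
    for (i in seq_along(state$ages)) {
      c0 <- cells[[paste(g, i)]]
      out[g, i, ] <- c(c0$never, c0$daily, c0$nondaily, c0$fd, c0$fn)
    }
  }
  out
}

# scalar replica of one full scenario year: state aging, transitions,
# population step (identity policy modifiers)
oracle_scenario_year <- function(cells, pop_counts, mort, mig, births,
                                 widths, rates_cess, relapse,
                                 init_d, init_n, n_ages) {
  # survivor counts per cell
  surv <- matrix(0, 2, n_ages)
  for (g in 1:2) {
    for (i in seq_len(n_ages)) {
      s <- pop_counts[g, i] * (1 - mort[g, i]) + mig[g, i]
      surv[g, i] <- max(s, 0)
    }
  }
  # state aging: shift fractions up; last age survivor-weighted merge;
  # first age reset to never
  new_cells <- cells
  for (g in 1:2) {
    for (i in seq_len(n_ages)) {
      if (i == 1) {
        new_cells[[paste(g, i)]] <- list(
          never = 1, daily = 0, nondaily = 0,
          fd = numeric(length(widths)), fn = numeric(length(widths)))
      } else if (i < n_ages) {
        new_cells[[paste(g, i)]] <- cells[[paste(g, i - 1)]]
      } else {
        a <- cells[[paste(g, i - 1)]]
        b <- cells[[paste(g, i)]]
        wa <- surv[g, i - 1]
        wb <- surv[g, i]
        mix <- function(x, y) (x * wa + y * wb) / (wa + wb)
        new_cells[[paste(g, i)]] <- list(
          never = mix(a$never, b$never), daily = mix(a$daily, b$daily),
          nondaily = mix(a$nondaily, b$nondaily),
          fd = mix(a$fd, b$fd), fn = mix(a$fn, b$fn))
      }
    }
  }
  # transitions per cell
  for (g in 1:2) {
    for (i in seq_len(n_ages)) {
      new_cells[[paste(g, i)]] <- oracle_step_cell(
        new_cells[[paste(g, i)]], widths,
        init_d[g, i], init_n[g, i], rates_cess[g, i], relapse,
        1, 1, 1, 1, 0, 0)
    }
  }
  # population step
  new_pop <- pop_counts
  for (g in 1:2) {
    for (i in seq_len(n_ages)) {
      if (i == 1) new_pop[g, i] <- births[g]
      else if (i < n_ages) new_pop[g, i] <- surv[g, i - 1]
      else new_pop[g, i] <- surv[g, i - 1] + surv[g, i]
    }
  }
  list(cells = new_cells, pop = new_pop)
}
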