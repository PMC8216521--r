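# Smoking-state recursion. Within a simulated year the transitions are
# applied in a fixed, documented order:
#   1. quit-class aging (proportional outflow 1 / class width),
#   2. initiation (never -> daily/nondaily, initiation window only),
#   3. cessation (daily/nondaily -> former <1 year),
#   4. relapse (former -> originating smoker type, per quit class),
#   5. first-year policy prevalence shock (daily/nondaily -> former <1 year).
# Order matters at the second decimal; see the methods vignette.

fd_names <- function(state) paste0("fd_", state$quit_classes)
fn_names <- function(state) paste0("fn_", state$quit_classes)

#' Identity policy modifiers (no policy change)
#'
#' @param ages ages of the target state grid.
#' @param year calendar year the modifiers apply to.
#' @return a `policy_modifiers` object with zero shocks and unit
#'   multipliers.
#' @export
identity_modifiers <- function(ages = DEFAULT_AGES, year = NA_integer_) {
  n <- length(ages)
  z <- array(0, dim = c(2L, n, 2L),
             dimnames = list(gender = GENDERS, age = as.character(ages),
                             type = c("daily", "nondaily")))
  one <- z + 1
  structure(list(year = year, shock = z, init_mult = one, cess_mult = one,
                 ages = as.integer(ages)),
            class = "policy_modifiers")
}

#' Age the smoking-state grid alongside the population
#'
#' Cohorts carry their state fractions up one age. The open-ended last age
#' is the survivor-weighted mixture of the penultimate-age cohort and the
#' cohort already in it; the new age-0 cohort is entirely never smokers.
#'
#' @param state a [smoking_state_grid()].
#' @param pop the [population_grid()] for the same year (supplies the
#'   survivor weights for the open-ended age).
#' @param rates the [vital_rates()] used to advance `pop`.
#' @return a `smoking_state_grid` for `state$year + 1`.
#' @export
age_states <- function(state, pop, rates) {
  stopifnot(inherits(state, "smoking_state_grid"))
  if (state$year != pop$year) stop("state and population years differ")
  cell <- survivor_cells(pop, rates, warn = FALSE)
  f <- state$frac
  n <- length(state$ages)
  new <- f
  if (n > 1L) {
    new[, 2:n, ] <- f[, 1:(n - 1L), ]
    w_pen <- cell[, n - 1L]
    w_top <- cell[, n]
    for (g in 1:2) {
      tot <- w_pen[g] + w_top[g]
      new[g, n, ] <- if (tot > 0) {
        (f[g, n - 1L, ] * w_pen[g] + f[g, n, ] * w_top[g]) / tot
      } else {
        f[g, n, ]
      }
    }
  }
  new[, 1L, ] <- 0
  new[, 1L, "never"] <- 1
  smoking_state_grid(new, state$year + 1L, state$ages, state$quit_classes,
                     state$quit_widths)
}

#' Apply one year of initiation, cessation, relapse and policy shocks
#'
#' Evolves the state occupancy of every (gender, age) cell through the
#' five-stage annual transition order (see the file header and the methods
#' vignette). Fractions are conserved exactly by construction and
#' re-validated to 1e-9.
#'
#' @param state a [smoking_state_grid()].
#' @param rates a [transition_rates()] on the same ages.
#' @param modifiers a `policy_modifiers` object (see [build_modifiers()]);
#'   defaults to the identity.
#' @return the evolved `smoking_state_grid` (same year label: aging across
#'   calendar years is the separate [age_states()] step).
#' @export
step_states <- function(state, rates, modifiers = NULL) {
  stopifnot(inherits(state, "smoking_state_grid"),
            inherits(rates, "transition_rates"))
  if (is.null(modifiers)) modifiers <- identity_modifiers(state$ages)
  if (!identical(as.integer(state$ages), modifiers$ages)) {
    stop("modifiers cover different ages than the state grid")
  }
  if (any(modifiers$init_mult < 0) || any(modifiers$cess_mult < 0)) {
    stop("policy multipliers must be non-negative")
  }
  if (any(modifiers$shock >= 1)) stop("prevalence shock must be below 1")
  nq <- length(state$quit_classes)
  w <- state$quit_widths
  f <- state$frac
  never <- f[, , "never", drop = TRUE]
  daily <- f[, , "daily", drop = TRUE]
  nond <- f[, , "nondaily", drop = TRUE]
  fd <- f[, , fd_names(state), drop = FALSE]
  fn <- f[, , fn_names(state), drop = FALSE]
  if (length(state$ages) == 1L) {  # keep matrix shape for single-age toys
    dim(never) <- dim(daily) <- dim(nond) <- c(2L, 1L)
  }

  # 1. quit-class aging: proportional outflow 1/width, last class absorbing
  outflow <- function(m) {
    out <- sweep(m, 3L, ifelse(is.finite(w), 1 / w, 0), "*")
    res <- m - out
    if (nq > 1L) res[, , 2:nq] <- res[, , 2:nq] + out[, , 1:(nq - 1L)]
    res
  }
  fd <- outflow(fd)
  fn <- outflow(fn)

  # 2. initiation (never -> current), initiation window only
  inc_d <- never * rates$initiation_daily * modifiers$init_mult[, , "daily"]
  inc_n <- never * rates$initiation_nondaily *
    modifiers$init_mult[, , "nondaily"]
  over <- (inc_d + inc_n) > never + 1e-12
  if (any(over)) stop("initiation exceeds the never-smoker pool")
  never <- never - inc_d - inc_n
  daily <- daily + inc_d
  nond <- nond + inc_n

  # 3. cessation (current -> former, <1 year class)
  quit_d <- daily * rates$cessation * modifiers$cess_mult[, , "daily"]
  quit_n <- nond * rates$cessation * modifiers$cess_mult[, , "nondaily"]
  if (any(quit_d > daily + 1e-12) || any(quit_n > nond + 1e-12)) {
    stop("cessation flow exceeds current smokers (multiplier too large)")
  }
  daily <- daily - quit_d
  nond <- nond - quit_n
  fd[, , 1L] <- fd[, , 1L] + quit_d
  fn[, , 1L] <- fn[, , 1L] + quit_n

  # 4. relapse (former -> originating smoker type)
  rel_d <- sweep(fd, 3L, rates$relapse, "*")
  rel_n <- sweep(fn, 3L, rates$relapse, "*")
  fd <- fd - rel_d
  fn <- fn - rel_n
  daily <- daily + apply(rel_d, c(1L, 2L), sum)
  nond <- nond + apply(rel_n, c(1L, 2L), sum)

  # 5. first-year policy prevalence shock (current -> former, <1 year)
  shock_d <- daily * modifiers$shock[, , "daily"]
  shock_n <- nond * modifiers$shock[, , "nondaily"]
  daily <- daily - shock_d
  nond <- nond - shock_n
  fd[, , 1L] <- fd[, , 1L] + shock_d
  fn[, , 1L] <- fn[, , 1L] + shock_n

  new <- f
  new[, , "never"] <- never
  new[, , "daily"] <- daily
  new[, , "nondaily"] <- nond
  new[, , fd_names(state)] <- fd
  new[, , fn_names(state)] <- fn
  if (any(new < -1e-12) || any(new > 1 + 1e-12)) {
    stop("transition produced a fraction outside [0, 1]; ",
         "model misconfiguration")
  }
  smoking_state_grid(pmin(pmax(new, 0), 1), state$year, state$ages,
                     state$quit_classes, state$quit_widths)
}

#' Derive initiation rates from a baseline prevalence profile
#'
#' Initiation at age a is the positive difference between baseline
#' prevalence at age a and at age a-1, computed separately for daily and
#' nondaily smoking, expressed as a probability by dividing by the
#' never-smoker share at age a-1.
#'
#' @param baseline a [smoking_state_grid()] covering the initiation window.
#' @param window ages receiving initiation (default 15:28; the rate at the
#'   first window age absorbs the increment from the age below it).
#' @return list with 2 x n matrices `initiation_daily` and
#'   `initiation_nondaily` (zero outside `window`).
#' @export
derive_initiation <- function(baseline, window = 15:28) {
  stopifnot(inherits(baseline, "smoking_state_grid"))
  ages <- baseline$ages
  if (!all(window %in% ages) || !all((window - 1L) %in% ages)) {
    stop("baseline must cover the initiation window and the age below it")
  }
  f <- baseline$frac
  out_d <- matrix(0, 2L, length(ages),
                  dimnames = list(GENDERS, as.character(ages)))
  out_n <- out_d
  any_pos <- FALSE
  for (ty in c("daily", "nondaily")) {
    for (g in 1:2) {
      p <- f[g, , ty]
      nv <- f[g, , "never"]
      for (a in window) {
        i <- match(a, ages)
        diff <- p[i] - p[i - 1L]
        if (diff > 0) {
          if (nv[i - 1L] <= 0) {
            warning("prevalence increases at age ", a,
                    " but the never-smoker pool is empty")
            next
          }
          rate <- diff / nv[i - 1L]
          if (ty == "daily") out_d[g, i] <- rate else out_n[g, i] <- rate
          any_pos <- TRUE
        }
      }
    }
  }
  if (!any_pos) {
    warning("no positive prevalence increments; no net initiation derivable")
  }
  list(initiation_daily = out_d, initiation_nondaily = out_n)
}

#' Cessation rate from recent-quitter and current-smoker counts
#'
#' The annual cessation probability is the number of former smokers who
#' quit within the last year divided by the smokers at risk the previous
#' year (current smokers plus those recent quitters). The same rate is
#' applied to daily and nondaily smokers.
#'
#' @param smokers,recent_quitters numeric vectors/matrices of matching
#'   shape (counts or fractions; the rate is scale invariant).
#' @return cessation rates of the same shape; cells with a zero denominator
#'   return 0 with a warning.
#' @export
derive_cessation <- function(smokers, recent_quitters) {
  if (!all(dim(as.matrix(smokers)) == dim(as.matrix(recent_quitters)))) {
    stop("smokers and recent_quitters must have the same shape")
  }
  denom <- smokers + recent_quitters
  if (any(denom == 0)) warning("zero denominator; cessation rate set to 0")
  ifelse(denom > 0, recent_quitters / denom, 0)
}

#' Cessation rates implied by a baseline state grid
#'
#' Applies [derive_cessation()] cell-wise, with recent quitters taken from
#' the <1 year former compartments (daily plus nondaily).
#'
#' @param state a [smoking_state_grid()].
#' @param warn_zero warn about zero denominators at ages 15 and above.
#' @return 2 x n matrix of cessation rates.
#' @export
derive_cessation_from_state <- function(state, warn_zero = FALSE) {
  f <- state$frac
  lt1 <- f[, , paste0("fd_", state$quit_classes[1L])] +
    f[, , paste0("fn_", state$quit_classes[1L])]
  cur <- f[, , "daily"] + f[, , "nondaily"]
  denom <- cur + lt1
  if (warn_zero && any(denom[, state$ages >= 15] == 0)) {
    warning("zero smoker denominator at some adult ages; rate set to 0")
  }
  out <- ifelse(denom > 0, lt1 / denom, 0)
  matrix(out, 2L, length(state$ages),
         dimnames = list(GENDERS, as.character(state$ages)))
}

#' Population-weighted prevalence over an age band
#'
#' @param state a [smoking_state_grid()].
#' @param pop the matching [population_grid()] supplying the weights.
#' @param band integer vector of ages (default 15:65, the model's standard
#'   reporting band).
#' @param types smoker types to summarise.
#' @return data frame with columns gender, type, prevalence.
#' @export
prevalence_summary <- function(state, pop, band = 15:65,
                               types = c("daily", "nondaily")) {
  keep <- intersect(band, state$ages)
  if (!length(keep)) stop("empty age band")
  idx <- as.character(keep)
  rows <- list()
  for (g in GENDERS) {
    wts <- pop$counts[g, idx]
    for (ty in types) {
      p <- if (sum(wts) > 0) {
        sum(state$frac[g, idx, ty] * wts) / sum(wts)
      } else {
        mean(state$frac[g, idx, ty])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, type = ty, prevalence = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
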