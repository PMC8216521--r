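# Policy engine: converts policy timelines into first-year prevalence
# shocks and ongoing initiation/cessation multipliers.
#
# Conventions. Effect sizes are stored signed, as in the published effect
# table: prevalence and initiation effects are <= 0 (reductions), cessation
# effects >= 0 (increases). Within a policy family, sub-effects compose
# multiplicatively: combined = prod(1 + e_i) - 1. First-year shocks use the
# ratio form 1 - (1 - e_new)/(1 - e_old) on the positive-reduction scale,
# so repeated level upgrades compose to the same result as a single jump.
# Ongoing multipliers are expressed relative to the scenario baseline-year
# effect, making status quo and counterfactual directly comparable.

#' Load a policy effect-size table
#'
#' Reads the CSV shipped with the package (or a user-edited copy) holding
#' the per-policy, per-level effect magnitudes, the age-specific price
#' elasticities and the youth-access effects by age band.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return object of class `effect_table`.
#' @export
read_effect_table <- function(path = system.file("extdata",
                                                 "effect_sizes.csv",
                                                 package = "smokesim")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("family", "item", "prevalence", "initiation", "cessation")
  if (!all(needed %in% names(raw))) {
    stop("effect table must have columns ", paste(needed, collapse = ", "))
  }
  effects <- list()
  elast <- list()
  youth <- list()
  for (i in seq_len(nrow(raw))) {
    fam <- raw$family[i]
    item <- raw$item[i]
    if (fam == "price") {
      elast[[item]] <- raw$prevalence[i]
    } else if (fam == "youth_access") {
      youth[[item]] <- c(prevalence = raw$prevalence[i],
                         initiation = raw$initiation[i])
    } else {
      effects[[fam]][[item]] <- c(prevalence = raw$prevalence[i],
                                  initiation = raw$initiation[i],
                                  cessation = raw$cessation[i])
    }
  }
  structure(list(effects = effects, elasticity = elast, youth = youth),
            class = "effect_table")
}

#' @rdname read_effect_table
#' @export
default_effect_table <- function() {
  read_effect_table()
}

#' Age-specific price elasticity of smoking prevalence
#'
#' @param table an `effect_table`.
#' @param ages integer ages.
#' @return elasticities (<= 0); zero below age 14.
#' @export
elasticity_at <- function(table, ages) {
  e <- table$elasticity
  out <- numeric(length(ages))
  out[ages >= 14 & ages <= 17] <- e$elasticity_ages_14_17
  out[ages >= 18 & ages <= 24] <- e$elasticity_ages_18_24
  out[ages >= 25 & ages <= 34] <- e$elasticity_ages_25_34
  out[ages >= 35 & ages <= 64] <- e$elasticity_ages_35_64
  out[ages >= 65] <- e$elasticity_ages_65p
  out
}

#' Scale a policy effect for imperfect enforcement and publicity
#'
#' Effects are halved in the complete absence of enforcement/publicity
#' (score 0) and reach full strength at score 10, with a linear ramp in
#' between.
#'
#' @param effect signed effect size.
#' @param score enforcement/publicity score on a 0-10 scale.
#' @export
enforcement_scaling <- function(effect, score) {
  if (any(score < 0 | score > 10)) stop("enforcement score must be in [0, 10]")
  effect * (0.5 + 0.5 * score / 10)
}

#' Scale a policy effect for partial population coverage
#'
#' @param effect signed effect size.
#' @param coverage fraction of the population covered, in [0, 1].
#' @export
coverage_scaling <- function(effect, coverage) {
  if (any(coverage < 0 | coverage > 1)) stop("coverage must be in [0, 1]")
  effect * coverage
}

#' Combine policy reductions non-additively
#'
#' Policy effects are not additive: the combined survival multiplier is the
#' product of the individual (1 - e) factors, so the combined reduction is
#' always no larger than the sum of the individual reductions.
#'
#' @param effects numeric vector of reductions, each below 1 (expressed as
#'   positive fractions).
#' @return the combined multiplier `prod(1 - effects)`.
#' @export
combine_policies <- function(effects) {
  if (!length(effects)) return(1)
  if (any(effects >= 1)) stop("policy reduction must be below 1")
  prod(1 - effects)
}

# signed multiplicative composition: prod(1 + e_i) - 1
compose_signed <- function(parts) {
  out <- 1
  for (p in parts) out <- out * (1 + p)
  out - 1
}

# publicity discount for cessation financial coverage
financial_publicity_factor <- function(publicity) {
  switch(publicity,
         high = 1, moderate = 1 - 0.125, low = 1 - 0.1875, none = 1 - 0.1875,
         stop("unknown financial-coverage publicity level: ", publicity))
}

# quit-line tier scaling: full effect for active with follow-up,
# 2/3 if proactive, 1/3 if passive ("low"), 0 if absent
quitline_tier_factor <- function(tier) {
  switch(tier,
         active = 1, proactive = 2 / 3, passive = 1 / 3, low = 1 / 3,
         none = 0,
         stop("unknown quit-line tier: ", tier))
}

#' Effective policy-family effects in a given year
#'
#' Computes the fully scaled (coverage, enforcement, level mix, nondaily
#' scaling) signed effect of one policy family at one year, per age.
#'
#' @param family one of `health_warnings`, `smoke_free`, `media_campaign`,
#'   `marketing_restrictions`, `cessation_treatment`, `youth_access`,
#'   `price`.
#' @param timeline a [policy_timeline()].
#' @param table an `effect_table`.
#' @param year calendar year.
#' @param ages ages to evaluate at.
#' @param scale multiplier in [0, 1] applied to every effect size (the
#'   nondaily sensitivity dial).
#' @return list of per-age vectors `prev` (reduction, >= 0 when the effect
#'   reduces prevalence), `init` (signed), `cess` (signed).
#' @export
family_effects <- function(family, timeline, table, year,
                           ages = DEFAULT_AGES, scale = 1) {
  n <- length(ages)
  zero <- list(prev = numeric(n), init = numeric(n), cess = numeric(n))
  pol <- timeline$policies[[family]]
  const3 <- function(eff) {
    list(prev = rep(-eff[["prevalence"]], n),
         init = rep(eff[["initiation"]], n),
         cess = rep(eff[["cessation"]], n))
  }
  switch(family,
    health_warnings = {
      lvl <- tl_at(pol$level, year, "health_warnings level")
      const3(table$effects$health_warnings[[lvl]] * scale)
    },
    media_campaign = {
      lvl <- tl_at(pol$level, year, "media_campaign level")
      const3(table$effects$media_campaign[[lvl]] * scale)
    },
    smoke_free = {
      enf <- enforcement_scaling(1, pol$enforcement %||% 10)
      parts_p <- list(); parts_i <- list(); parts_c <- list()
      for (sub in names(pol$coverage)) {
        cov <- tl_at(pol$coverage[[sub]], year,
                     paste0("smoke_free ", sub, " coverage"))
        eff <- table$effects$smoke_free[[sub]] * scale * cov * enf
        parts_p <- c(parts_p, eff[["prevalence"]])
        parts_i <- c(parts_i, eff[["initiation"]])
        parts_c <- c(parts_c, eff[["cessation"]])
      }
      list(prev = rep(-compose_signed(parts_p), n),
           init = rep(compose_signed(parts_i), n),
           cess = rep(compose_signed(parts_c), n))
    },
    marketing_restrictions = {
      enf <- enforcement_scaling(1, pol$enforcement %||% 10)
      mix <- tl_at_list(pol$mix, year, "marketing_restrictions mix")
      eff <- c(prevalence = 0, initiation = 0, cessation = 0)
      for (lvl in names(mix)) {
        eff <- eff + table$effects$marketing_restrictions[[lvl]] * mix[[lvl]]
      }
      const3(eff * enf * scale)
    },
    cessation_treatment = {
      # a timeline may request the published full-bundle row directly
      # (its printed magnitude is not the product of the components)
      if (!is.null(pol$bundle)) {
        bundle <- tl_at(pol$bundle, year, "cessation_treatment bundle")
        if (bundle == "none") return(zero)
        return(const3(table$effects$cessation_treatment[[bundle]] * scale))
      }
      avail <- tl_at(pol$pharmacotherapy, year,
                     "cessation_treatment pharmacotherapy")
      cov <- tl_at(pol$financial_coverage, year,
                   "cessation_treatment financial_coverage")
      pub <- financial_publicity_factor(pol$financial_publicity %||% "high")
      ql <- quitline_tier_factor(
        tl_at(pol$quitline, year, "cessation_treatment quitline"))
      idx <- tl_at(pol$brief_index, year, "cessation_treatment brief_index")
      tab <- table$effects$cessation_treatment
      comp <- list(tab$pharmacotherapy * avail,
                   tab$financial_coverage * cov * pub,
                   tab$quitline * ql,
                   tab$brief_intervention * idx)
      comp <- lapply(comp, function(x) x * scale)
      list(prev = rep(-compose_signed(lapply(comp, `[[`, "prevalence")), n),
           init = rep(compose_signed(lapply(comp, `[[`, "initiation")), n),
           cess = rep(compose_signed(lapply(comp, `[[`, "cessation")), n))
    },
    youth_access = {
      tier <- tl_at(pol$level, year, "youth_access level")
      if (tier == "none") return(zero)
      prev <- numeric(n); init <- numeric(n)
      y1 <- table$youth[[paste0(tier, "_ages_14_15")]]
      y2 <- table$youth[[paste0(tier, "_ages_16_17")]]
      b1 <- ages %in% 14:15
      b2 <- ages %in% 16:17
      prev[b1] <- -y1[["prevalence"]] * scale
      prev[b2] <- -y2[["prevalence"]] * scale
      init[b1] <- y1[["initiation"]] * scale
      init[b2] <- y2[["initiation"]] * scale
      list(prev = prev, init = init, cess = numeric(n))
    },
    price = {
      series <- timeline$price
      if (is.null(series)) return(zero)
      yrs <- as.integer(names(series))
      base <- timeline$baseline_year
      el <- elasticity_at(table, ages) * scale
      rel <- rep(1, n)
      if (year > base) {
        for (t in seq(base + 1L, year)) {
          p_now <- tl_at(series, t, "price")
          p_prev <- tl_at(series, t - 1L, "price")
          if (p_now <= 0 || p_prev <= 0) stop("prices must be positive")
          rel <- rel * (1 + el * (p_now - p_prev) / p_prev)
        }
      }
      init <- ifelse(ages <= 24, rel - 1, 0)
      list(prev = 1 - rel, init = init, cess = numeric(n))
    },
    stop("unknown policy family: ", family)
  )
}

#' First-year prevalence shock from a policy level change
#'
#' When a family's effective prevalence reduction rises from e_old (last
#' year) to e_new, the fraction `1 - (1 - e_new)/(1 - e_old)` of current
#' smokers is moved to the recently quit compartment in that year. Shocks
#' are one-way (a level decrease applies no positive "un-shock"), except
#' for price, which is symmetric by default.
#'
#' @inheritParams family_effects
#' @return per-age shock fractions.
#' @export
incremental_shock <- function(family, year, timeline, table,
                              ages = DEFAULT_AGES, scale = 1) {
  if (year <= timeline$baseline_year) return(numeric(length(ages)))
  e_new <- family_effects(family, timeline, table, year, ages, scale)$prev
  e_old <- family_effects(family, timeline, table, year - 1L, ages,
                          scale)$prev
  if (any(e_new >= 1) || any(e_old >= 1)) {
    stop("effective prevalence reduction must be below 1")
  }
  shock <- 1 - (1 - e_new) / (1 - e_old)
  symmetric <- family == "price" && isTRUE(timeline$price_symmetric %||% TRUE)
  if (!symmetric) shock <- pmax(shock, 0)
  shock
}

#' Ongoing initiation and cessation multipliers for a policy family
#'
#' In years after the first, a policy acts through reduced initiation and
#' increased cessation. The multipliers are expressed relative to the
#' baseline-year effect: `(1 + i_now)/(1 + i_base)` for initiation (i <= 0)
#' and `(1 + c_now)/(1 + c_base)` for cessation (c >= 0); both are 1 when
#' the level equals the baseline level.
#'
#' @inheritParams family_effects
#' @return list of per-age vectors `initiation` and `cessation`.
#' @export
ongoing_multipliers <- function(family, year, timeline, table,
                                ages = DEFAULT_AGES, scale = 1) {
  now <- family_effects(family, timeline, table, year, ages, scale)
  base <- family_effects(family, timeline, table, timeline$baseline_year,
                         ages, scale)
  list(initiation = (1 + now$init) / (1 + base$init),
       cessation = (1 + now$cess) / (1 + base$cess))
}

#' Prevalence change implied by a price change
#'
#' Converts a year-over-year relative price change into a relative
#' prevalence change through the age-specific elasticity.
#'
#' @param price_t,price_prev real cigarette prices (must be positive).
#' @param age age (scalar or vector).
#' @param table an `effect_table`.
#' @return relative prevalence change (negative when prices rise).
#' @export
price_modifier <- function(price_t, price_prev, age,
                           table = default_effect_table()) {
  if (any(price_t <= 0) || any(price_prev <= 0)) {
    stop("prices must be positive")
  }
  elasticity_at(table, age) * (price_t - price_prev) / price_prev
}

#' Youth-access effects for an enforcement tier and age
#'
#' @param level `strong`, `moderate`, `low`, or `none`.
#' @param age age (scalar or vector); zero effect at ages 18 and over.
#' @param table an `effect_table`.
#' @return matrix with columns `prevalence` and `initiation` (signed).
#' @export
youth_access_modifier <- function(level, age,
                                  table = default_effect_table()) {
  out <- matrix(0, length(age), 2L,
                dimnames = list(NULL, c("prevalence", "initiation")))
  if (level == "none") return(out)
  y1 <- table$youth[[paste0(level, "_ages_14_15")]]
  y2 <- table$youth[[paste0(level, "_ages_16_17")]]
  if (is.null(y1) || is.null(y2)) stop("unknown youth-access level: ", level)
  out[age %in% 14:15, ] <- rep(y1, each = sum(age %in% 14:15))
  out[age %in% 16:17, ] <- rep(y2, each = sum(age %in% 16:17))
  out
}

#' Assemble the policy modifiers for one simulated year
#'
#' Computes every family's first-year shock and ongoing multipliers for
#' `year`, combines shocks non-additively (product of survival factors) and
#' multiplies the initiation/cessation multipliers across families. The
#' timeline's `nondaily_scale` is applied to every effect size for the
#' nondaily smoker type.
#'
#' @param timeline a [policy_timeline()].
#' @param table an `effect_table`.
#' @param year calendar year.
#' @param ages ages of the target state grid.
#' @return a `policy_modifiers` object with `[gender, age, type]` arrays
#'   `shock`, `init_mult`, `cess_mult`.
#' @export
build_modifiers <- function(timeline, table, year, ages = DEFAULT_AGES) {
  mods <- identity_modifiers(ages, year)
  families <- names(timeline$policies)
  if (!is.null(timeline$price) && length(timeline$price)) {
    families <- c(families, "price")
  }
  scales <- c(daily = 1, nondaily = timeline$nondaily_scale %||% 1)
  for (ty in c("daily", "nondaily")) {
    sc <- scales[[ty]]
    surv <- rep(1, length(ages))
    im <- rep(1, length(ages))
    cm <- rep(1, length(ages))
    for (fam in families) {
      shock <- incremental_shock(fam, year, timeline, table, ages, sc)
      mult <- ongoing_multipliers(fam, year, timeline, table, ages, sc)
      surv <- surv * (1 - shock)
      im <- im * mult$initiation
      cm <- cm * mult$cessation
    }
    for (g in 1:2) {
      mods$shock[g, , ty] <- 1 - surv
      mods$init_mult[g, , ty] <- im
      mods$cess_mult[g, , ty] <- cm
    }
  }
  if (any(mods$init_mult < 0) || any(mods$cess_mult < 0)) {
    stop("policy multipliers must be non-negative")
  }
  mods
}
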