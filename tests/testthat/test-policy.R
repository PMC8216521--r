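tbl <- default_effect_table()

# a minimal one-policy timeline builder
warn_tl <- function(levels, baseline_year = 2002) {
  policy_timeline(list(health_warnings = list(level = levels)),
                  baseline_year = baseline_year)
}

test_that("enforcement scaling ramps linearly from half to full effect", {
  expect_equal(enforcement_scaling(-0.06, 10), -0.06)
  expect_equal(enforcement_scaling(-0.06, 0), -0.03)
  expect_equal(enforcement_scaling(-0.06, 4), -0.042)
  expect_error(enforcement_scaling(-0.06, 11), "0, 10")
})

test_that("coverage scaling is proportional", {
  expect_equal(coverage_scaling(-0.06, 1), -0.06)
  expect_equal(coverage_scaling(-0.06, 0), 0)
  expect_equal(coverage_scaling(-0.06, 0.45), -0.027)
})

test_that("policy reductions combine as a product of survival factors", {
  expect_equal(combine_policies(numeric(0)), 1)
  expect_equal(combine_policies(0.04), 0.96)
  expect_equal(combine_policies(c(0.04, 0.02, 0.01)), 0.931392)
  expect_error(combine_policies(c(0.04, 1)), "below 1")

  set.seed(11)
  for (rep in 1:10) {
    e <- runif(5, 0, 0.3)
    expect_identical(combine_policies(e), combine_policies(sample(e)))
    # combined reduction never exceeds the sum of reductions
    expect_lte(1 - combine_policies(e), sum(e))
  }
})

test_that("first-year shocks follow the incremental ratio form", {
  tl <- warn_tl(c(`2002` = "low", `2004` = "moderate", `2010` = "high"))
  ages <- 30
  expect_equal(incremental_shock("health_warnings", 2003, tl, tbl, ages), 0)
  expect_equal(incremental_shock("health_warnings", 2004, tl, tbl, ages),
               1 - 0.98 / 0.99)
  expect_equal(incremental_shock("health_warnings", 2010, tl, tbl, ages),
               1 - 0.96 / 0.98)
  expect_equal(incremental_shock("health_warnings", 2011, tl, tbl, ages), 0)

  # from nothing straight to high: the full 4% in the upgrade year
  tl0 <- warn_tl(c(`2002` = "none", `2010` = "high"))
  expect_equal(incremental_shock("health_warnings", 2010, tl0, tbl, ages),
               0.04)
  # shocks are one-way: a downgrade applies no positive un-shock
  tld <- warn_tl(c(`2002` = "high", `2010` = "low"))
  expect_equal(incremental_shock("health_warnings", 2010, tld, tbl, ages), 0)
})

test_that("ongoing multipliers are relative to the baseline-year level", {
  tl <- warn_tl(c(`2002` = "low", `2010` = "high"))
  ages <- 30
  m09 <- ongoing_multipliers("health_warnings", 2009, tl, tbl, ages)
  expect_equal(m09$initiation, 1)
  expect_equal(m09$cessation, 1)
  m10 <- ongoing_multipliers("health_warnings", 2010, tl, tbl, ages)
  expect_equal(m10$initiation, 0.94 / 0.99)
  expect_equal(m10$cessation, 1.10 / 1.02)
})

test_that("the full cessation-treatment bundle row gives a 1.427 multiplier", {
  tl <- policy_timeline(list(cessation_treatment = list(
    bundle = c(`2002` = "none", `2007` = "all_combined"))),
    baseline_year = 2002)
  m <- ongoing_multipliers("cessation_treatment", 2010, tl, tbl, 30)
  expect_equal(m$cessation, 1.427)
  expect_equal(incremental_shock("cessation_treatment", 2007, tl, tbl, 30),
               0.0515)
})

test_that("cessation-treatment components compose multiplicatively", {
  tl <- policy_timeline(list(cessation_treatment = list(
    pharmacotherapy = c(`2002` = 1),
    financial_coverage = c(`2002` = 0, `2007` = 0.5),
    financial_publicity = "low",
    quitline = c(`2002` = "none", `2008` = "low"),
    brief_index = c(`2002` = 0.2))),
    baseline_year = 2002)
  eff <- family_effects("cessation_treatment", tl, tbl, 2010, 30)
  # financial: 12% x 0.5 coverage x (1 - 0.1875) publicity; quitline 1/3
  expected_cess <- (1 + 0.06) * (1 + 0.12 * 0.5 * 0.8125) *
    (1 + 0.075 / 3) * (1 + 0.08 * 0.2) - 1
  expect_equal(eff$cess, expected_cess)
})

test_that("smoke-free sub-bans are coverage- and enforcement-scaled", {
  tl <- policy_timeline(list(smoke_free = list(
    enforcement = 4,
    coverage = list(worksite = c(`2002` = 0, `2014` = 0.45)))),
    baseline_year = 2002)
  eff <- family_effects("smoke_free", tl, tbl, 2014, 30)
  expect_equal(eff$prev, 0.06 * 0.45 * 0.7)  # -1.89% contribution
  expect_equal(incremental_shock("smoke_free", 2014, tl, tbl, 30),
               0.06 * 0.45 * 0.7)
})

test_that("price changes act through age-specific elasticities", {
  expect_equal(price_modifier(30, 30, 40, tbl), 0)
  expect_equal(price_modifier(33, 30, 16, tbl), -0.04)
  expect_equal(price_modifier(36, 30, 40, tbl), -0.02)
  expect_error(price_modifier(0, 30, 40, tbl), "positive")

  tl <- policy_timeline(list(), baseline_year = 2002,
                        price = c(`2002` = 30, `2003` = 33))
  s <- incremental_shock("price", 2003, tl, tbl, c(16, 40))
  expect_equal(s, c(0.04, 0.01))
  # and the youth initiation channel tracks the cumulative price change
  m <- ongoing_multipliers("price", 2003, tl, tbl, c(16, 40))
  expect_equal(m$initiation, c(0.96, 1))
})

test_that("symmetric price drops reverse the shock; multipliers relax", {
  tl <- policy_timeline(list(), baseline_year = 2002,
                        price = c(`2002` = 30, `2003` = 33, `2004` = 30))
  s <- incremental_shock("price", 2004, tl, tbl, 40)
  expect_true(s < 0)
  m <- ongoing_multipliers("price", 2004, tl, tbl, 16)
  expect_equal(m$initiation, (1 - 0.4 * 0.1) * (1 + 0.4 * (3 / 33)))
})

test_that("youth-access effects apply only below age 18", {
  expect_equal(unname(youth_access_modifier("strong", 30, tbl)[1, ]),
               c(0, 0))
  expect_equal(unname(youth_access_modifier("strong", 15, tbl)[1, ]),
               c(-0.24, -0.24))
  expect_equal(unname(youth_access_modifier("low", 16, tbl)[1, ]),
               c(-0.02, -0.02))
})

test_that("marketing mixed levels are coverage-weighted", {
  tl <- policy_timeline(list(marketing_restrictions = list(
    enforcement = 5,
    mix = list(`2002` = list(minimal = 0.5),
               `2009` = list(moderate = 0.75, minimal = 0.25)))),
    baseline_year = 2002)
  eff <- family_effects("marketing_restrictions", tl, tbl, 2009, 30)
  expect_equal(eff$prev, (0.75 * 0.03 + 0.25 * 0.01) * 0.75)
  expect_equal(eff$init, -(0.75 * 0.04 + 0.25 * 0.01) * 0.75)
  expect_equal(eff$cess, 0.75 * 0.02 * 0.75)
})

test_that("a timeline frozen at baseline produces identity modifiers", {
  tl <- freeze_timeline(mexico_timeline())
  for (y in c(2003, 2010, 2018)) {
    mods <- build_modifiers(tl, tbl, y)
    expect_true(all(mods$shock == 0))
    expect_true(all(mods$init_mult == 1))
    expect_true(all(mods$cess_mult == 1))
  }
})

test_that("nondaily_scale halves the nondaily shock", {
  tl <- warn_tl(c(`2002` = "none", `2005` = "moderate"))
  tl$nondaily_scale <- 0.5
  mods <- build_modifiers(tl, tbl, 2005)
  expect_equal(unname(mods$shock[1, 1, "daily"]), 0.02)
  expect_equal(unname(mods$shock[1, 1, "nondaily"]), 0.01)
})

test_that("missing policy-years fail with a named error", {
  tl <- warn_tl(c(`2005` = "moderate"), baseline_year = 2002)
  expect_error(build_modifiers(tl, tbl, 2003),
               "health_warnings level.*at or before year 2003")
})

test_that("the Mexico preset encodes the implemented policy levels", {
  tl <- mexico_timeline()
  expect_equal(tl$baseline_year, 2002L)
  sf <- tl$policies$smoke_free
  expect_equal(smokesim:::tl_at(sf$coverage$worksite, 2012), 0.18)
  expect_equal(smokesim:::tl_at(sf$coverage$worksite, 2016), 0.45)
  expect_equal(smokesim:::tl_at(sf$coverage$restaurant, 2011), 0.60)
  expect_equal(smokesim:::tl_at(tl$policies$health_warnings$level, 2009),
               "moderate")
  expect_equal(smokesim:::tl_at(tl$policies$media_campaign$level, 2004),
               "none")
  expect_equal(smokesim:::tl_at(tl$policies$cessation_treatment$quitline,
                                2008), "low")
  expect_equal(sf$enforcement, 4)
  expect_equal(tl$policies$marketing_restrictions$enforcement, 5)
})
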