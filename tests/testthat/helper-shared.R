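# Shared expensive objects, built once per test run.

.shared <- new.env(parent = emptyenv())

shared_baseline <- function() {
  if (is.null(.shared$baseline)) .shared$baseline <- synth_baseline()
  .shared$baseline
}

# the full Mexico-preset comparison (status quo, counterfactual and all
# single-policy runs) to 2018
shared_cmp <- function() {
  if (is.null(.shared$cmp)) {
    cfg <- scenario_config(shared_baseline(), mexico_timeline(), 2018)
    .shared$cmp <- run_policy_comparison(cfg)
  }
  .shared$cmp
}

# a minimal scenario_result carrying fixed prevalences (for arithmetic
# tests of comparison operations)
fake_result <- function(values, year = 2018) {
  grid <- expand.grid(gender = c("male", "female"),
                      type = c("daily", "nondaily"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$year <- year
  grid$band <- "15-65"
  grid$prevalence <- values[paste(grid$gender, grid$type, sep = "_")]
  structure(list(prevalence = grid,
                 meta = list(start_year = year, end_year = year)),
            class = "scenario_result")
}
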