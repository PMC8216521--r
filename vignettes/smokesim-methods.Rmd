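---
title: "The smokesim model: structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smokesim model: structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesim)
```

## The model

`smokesim` is a discrete-time, first-order Markov cohort model of
cigarette smoking that distinguishes **daily** from **nondaily** (some but
not all days in the past 30) smokers. It simulates a national population
in annual steps from a 2002 baseline, and measures tobacco-control policy
impact as the *relative difference* in prevalence between a **status quo**
scenario (policies as actually implemented) and a **counterfactual**
(every policy frozen at its baseline-year level):

$$\mathrm{RD}(y, s) = 100 \times \frac{p_{\mathrm{sq}}(y, s) -
p_{\mathrm{cf}}(y, s)}{p_{\mathrm{cf}}(y, s)}\ \%$$

for year $y$ and stratum $s$ (gender × smoker type, reported on the ages
15–65 band by default). The model is fully deterministic: identical
configurations give bit-identical trajectories.

### State space

Each (gender, single age 0–85+) cell carries an occupancy vector over

* `never` — never smoker (everyone below age 15, by assumption),
* `daily`, `nondaily` — current smokers by type,
* `fd_*` / `fn_*` — former daily / former nondaily smokers binned by
  years since quitting: <1, 1–2, 3–5, 6–10, 11–15, 15+ years.

Fractions in every cell sum to 1 (validated to $10^{-9}$ after every
step). The quit-class bins are a configurable attribute of the state grid
(the defaults above follow common practice for this model family); relapse
probabilities and residual mortality risk are defined per bin.

### The annual step

Each simulated year applies, in this fixed order:

1. **Demographic aging.** The population advances one age through
   mortality, then net migration (absolute counts, may be negative;
   floored at zero with a warning), then the age shift (85+ is an
   open-ended absorbing compartment), then births into age 0. State
   fractions ride along with their cohorts; the 85+ cell becomes the
   survivor-weighted mixture of the incoming age-84 cohort and the cohort
   already there; the new age-0 cohort is entirely never smokers.
2. **Quit-class aging.** Each former-smoker bin loses the proportion
   1 / (bin width in years) to the next bin; the terminal bin absorbs.
3. **Initiation.** Never smokers become daily or nondaily smokers at the
   age-specific rate × the year's policy initiation multiplier,
   for ages 15–28 (the first increment, from age 14 to 15, is realised on
   that birthday transition so that under-15 cohorts remain never smokers
   exactly).
4. **Cessation.** Current smokers move to the <1-year former bin at the
   age-specific cessation rate × the policy cessation multiplier. The
   same rate applies to daily and nondaily smokers.
5. **Relapse.** Former smokers return to the smoker type they quit from,
   at the per-bin relapse probability.
6. **First-year policy shock.** When a policy's effective level rises in
   the year, the shock fraction of current smokers moves to the <1-year
   former bin.

The order matters at the second decimal of the resulting prevalences and
is therefore fixed and tested against an independently coded scalar
recurrence (agreement to $10^{-12}$ over ten years on a reduced
configuration).

Mortality is applied uniformly across smoking states in the prevalence
accounting; differential mortality by smoking status enters only the
death accounting (below). This keeps prevalence dynamics and
smoking-attributable deaths separable, at the cost of ignoring the slow
compositional drift that higher smoker mortality would induce in
old-age prevalence — a documented approximation.

### Transition rates from a baseline cross-section

* **Initiation** at age $a$ is the positive difference between baseline
  prevalence at $a$ and at $a-1$ (separately for daily and nondaily),
  divided by the never-smoker share at $a-1$; rates are zero outside the
  15–28 window. Running a cohort forward with these rates and no
  cessation reproduces the baseline age profile exactly, which is tested.
* **Cessation** is recent quitters over smokers at risk:
  $q = n_{\mathrm{quit,<1y}} / (n_{\mathrm{smokers}} +
  n_{\mathrm{quit,<1y}})$, scale invariant, assigned to both smoker
  types.
* **Relapse** rates by years quit are not derivable from a single
  cross-section; the shipped defaults (0.50, 0.15, 0.05, 0.02, 0.01,
  0.005 per year for the six bins) encode the stylised facts of the
  cessation literature — most unaided quit attempts fail within the first
  year, and relapse hazard falls steeply with abstinence duration. They
  are explicitly synthetic, configurable, and not taken from any single
  study.

## The policy engine

Policy effect sizes live in an editable CSV
(`system.file("extdata", "effect_sizes.csv", package = "smokesim")`), one
row per policy level: a prevalence effect (≤ 0), an initiation effect
(≤ 0) and a cessation effect (≥ 0). Where the source table quotes a
single number for a level, the same magnitude applies to all three
channels; where it splits them (marketing, warnings, cessation
treatment), the split values are used. Scalings:

* **Coverage**: effects multiply by the covered population fraction.
* **Enforcement/publicity**: effects multiply by
  $0.5 + 0.5 \times \mathrm{score}/10$ — half strength with no
  enforcement, full at 10/10, linear in between (the same ramp is assumed
  for every family that takes a score).
* **Mixed levels** (marketing): the coverage-weighted average of the
  level effects.
* **Cessation treatment** composes pharmacotherapy availability,
  financial coverage (discounted 12.5% / 18.75% under moderate / low
  publicity), the quit line (scaled 1, 2/3, 1/3 for active, proactive,
  passive tiers) and brief interventions (scaled by the advice index)
  multiplicatively. The published "all policies combined" row is *not*
  the product of its components (−5.15%, +42.7% vs the composed −4.91%,
  +37.8%); it is shipped as its own level, selectable via a `bundle`
  timeline entry, and the discrepancy is left as printed.
* **Price** acts through age-band elasticities (−0.4 / −0.3 / −0.2 /
  −0.1 / −0.2 for ages 14–17 / 18–24 / 25–34 / 35–64 / 65+) on
  year-over-year relative changes in the real price, and scales youth
  (≤ 24) initiation by the cumulative relative change. Price decreases
  are symmetric by default (configurable to floor at zero).
* **Youth access** affects prevalence and initiation below age 18 only,
  by enforcement tier and age band (14–15 / 16–17).

**First-year shocks.** When a family's effective prevalence reduction
rises from $e_{\mathrm{old}}$ to $e_{\mathrm{new}}$, the fraction
$1 - (1 - e_{\mathrm{new}})/(1 - e_{\mathrm{old}})$ of current smokers is
moved to the <1-year former bin that year. The ratio form is the key
interpretation choice: repeated upgrades compose to exactly the same
total as a single jump to the final level. Shocks are one-way — a level
decrease applies no positive "un-shock" (price excepted, see above).

**Ongoing multipliers.** In later years the policy acts through
initiation and cessation multipliers relative to the baseline-year
effect: $(1 + i_{\mathrm{now}})/(1 + i_{\mathrm{base}})$ and
$(1 + c_{\mathrm{now}})/(1 + c_{\mathrm{base}})$, both exactly 1 while
the level stays at its baseline value. This referencing makes status quo
and counterfactual directly comparable.

**Combination.** Policies are not additive: shocks combine as
$1 - \prod_f (1 - s_f)$ and multipliers multiply across families, so the
combined reduction never exceeds the sum of the individual reductions.
The timeline's `nondaily_scale` (default 1.0, 0.5 in the half-effect
sensitivity setting) multiplies every effect size for the nondaily type
before any of the above.

### A note on type coupling

Daily and nondaily initiation draw on the *shared* never-smoker pool. A
policy that lowers daily initiation therefore leaves a marginally larger
pool feeding nondaily initiation, so the two types are weakly coupled:
with `nondaily_scale = 0` the nondaily status-quo trajectory matches the
counterfactual only to first order (residual relative differences around
0.3 percentage points against full impacts near 18), and the daily
trajectory is similarly almost — not exactly — invariant to the nondaily
dial. The tests assert these first-order statements.

## Scenarios, attribution, validation, deaths

`run_policy_comparison()` runs the status quo, the frozen counterfactual
and one single-policy run per family (everything else frozen). Because
effects combine non-additively, each policy's share is its single-policy
reduction divided by the *sum* of all single-policy reductions; shares
sum to 1 by construction. Every single-policy prevalence trajectory lies
between the counterfactual and the full status quo (tested year by year).

`validate_against_surveys()` compares model prevalence with survey point
estimates, reporting the relative error and a CI flag using **closed**
intervals (a model value exactly at a bound counts as within).

Smoking-attributable deaths use the excess-rate formulation: the
never-smoker death rate $r_n$ solves
$r_n \sum_s \mathrm{occ}_s \mathrm{RR}_s = m$ for the cell's overall
mortality $m$, status rates are $r_n \mathrm{RR}_s$, and attributable
deaths are $\mathrm{pop} \times \mathrm{occ}_s (r_s - r_n)$. This is
equivalent to the population-attributable-fraction formulation under the
balance equation, and reproduces overall deaths exactly when summed. The
shipped relative risks (daily ~1.4–2.5 by gender and age band, nondaily
lower, former-smoker excess decaying geometrically toward 1 across quit
bins) are synthetic editable defaults.

## The synthetic baseline

No deposited baseline microdata exist, so `synth_baseline()` builds every
input from smooth parametric shapes:

* **Population**: exponential pyramid, $10^6 e^{-0.015a}$ persons per
  gender at age $a$ (≈ 97 million total — a young, developing-country
  age structure); births hold the age-0 cohort size; migration zero by
  default.
* **Mortality**: infant component + background + late-age exponential
  rise, males 15% higher.
* **Smoking profile**: a smooth cosine ramp over ages 15–28, a plateau to
  age 50, then a linear decline to 40% of the plateau at 85+, with an
  optional multiplicative re-anchoring of the 65+ segment. Profiles are
  scaled (after shaping) so the population-weighted ages-15–65 prevalence
  matches the 2002 targets — male daily 21.3%, male nondaily 11.9%,
  female daily 6.9%, female nondaily 4.2% — to within $10^{-6}$,
  exactly as the calibration is linear.
* **Former smokers**: 0.5 × current smokers of the same type,
  distributed (0.08, 0.12, 0.15, 0.20, 0.20, 0.25) across the quit bins,
  which makes the derived cessation rate ≈ 3.8%/year — inside the
  empirically plausible 2–6% range.
* **Prices**: +8%/year real over 2003–2011 then flat (a doubling over the
  major tax-reform era); deterministic and clearly a stand-in for the
  unpublished official series.
* The optional **100-cigarette lifetime screen** rescales baseline
  prevalence per type (defaults: daily × 0.9, nondaily × 0.5, reflecting
  how much more often nondaily smokers fail the screen) without changing
  the age-profile shape.

Everything is a pure function of the spec; the only randomness in the
package is survey-noise synthesis, which is seed-controlled.

**What passing tests do and do not show.** The synthetic baseline
reproduces the calibrated gender totals, smooth age gradients and a
plausible former-smoker stock, but not survey weighting, cohort
irregularities, the secular rise in nondaily smoking, or
daily↔nondaily switching (the model has no switching transitions — an
acknowledged limitation of this model family). Reproducing the published
*non-price* single-policy relative differences therefore shows the policy
machinery and dynamics are right, not that the baseline matches any real
population; price-policy results depend on the synthetic price path and
are excluded from numerical comparison by design.

## Numerical choices

* Tolerances: cell occupancy validated to $10^{-9}$; oracle equivalence
  asserted at $10^{-12}$; calibration at $10^{-6}$.
* Degenerate inputs: zero cessation denominators give rate 0 with a
  warning; a zero counterfactual prevalence makes the relative difference
  `NA` with a warning; zero reference populations flag the band as
  undefined; negative survivor counts after out-migration are floored at
  0 with a warning.
* Hard errors: negative multipliers, shocks ≥ 1, effective reductions
  ≥ 1, initiation exceeding the never pool, cessation flows exceeding
  current smokers, missing policy-years (named), mismatched horizons.
* Reports round percentages to one decimal; raw values are retained
  internally.

Problem sizes used in the checks: the standard grid is 2 genders × 86
ages × 15 states; scenario comparisons run 2002–2018 (17 annual steps,
seven scenario runs in a few seconds); the conservation suite runs a
single 2002–2060 projection (58 steps); oracle comparisons use a 3-age,
2-quit-class configuration.

## Known limitations

* No daily↔nondaily switching, no intensity within daily smoking, no
  multiproduct or e-cigarette states.
* Vital rates are held constant over the projection (no mortality
  improvement or migration trends).
* Uniform mortality across smoking states inside the prevalence
  recursion (see above).
* Relapse rates and relative risks are synthetic defaults; results that
  depend on their absolute levels (death counts, long-horizon decay of
  policy shocks) should be treated as illustrative until replaced with
  estimates.
* The published scenario table prints slightly different smoke-free
  nondaily reductions in its text (−3.2/−3.4%) than in the table itself
  (−2.8%); the table values are used as the comparison points and the
  discrepancy is surfaced here rather than resolved. Worksite ban
  coverage for 2012–2013 is not stated in the source narrative and is
  carried forward at 18%.
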