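---
title: "Methods: the medication-based comorbidity index and the hip-fracture cohort models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the medication-based comorbidity index and the hip-fracture cohort models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each stage of the
package, the assumptions it makes, the tunable parameters and their
defaults, and the design decisions taken where the methodology left a
genuine choice. It states no empirical result that the package's tests do
not themselves compute.

## 1. The index

### Category mapping

Dispensings carry 7-character ATC codes (letter, two digits, two letters,
two digits, e.g. `N02AA01`). The index assigns every active substance to at
most one of 46 disease categories via a prefix table. Resolution is by
**longest matching prefix**, which lets a narrow entry (lithium, `N05AN`,
bipolar disorder) carve a sub-group out of a broader one (antipsychotics,
`N05A`) without ambiguity. `load_mapping()` rejects any table in which a
full code could resolve to two categories.

The shipped table (`default_mapping()`) is a reconstruction: the published
category list is public, but the exact national prefix table is not
reprinted in the open literature, so the packaged prefixes are plausible
rather than authoritative. All structural invariants (46 categories,
unambiguous resolution) are enforced and tested; analyses of real data
should substitute a validated mapping file.

### Severity-weight calibration

For calendar year $t$, let $D_i = 1$ if person $i$ dies in year $t+1$. The
calibration model is one logistic regression per year,

$$\operatorname{logit} P(D_i = 1) = \beta_0 + \beta_a \,\text{age}_i +
\beta_s \,\text{sex}_i + \sum_{c} \gamma_c \, X_{ic},$$

over subjects aged $\ge 50$ who filled at least one prescription in year
$t$, with $X_{ic}$ the 0/1 indicator that person $i$ filled category $c$
that year. $OR_c = e^{\gamma_c}$ with a two-sided Wald p-value is passed
through the step function `map_or_to_weight()`: weight 0 when $p > 0.10$;
otherwise $-1$ for $OR<1$, and weights 1–5 on half-open bands
$[1.0,1.2), [1.2,1.4), \dots, [1.8,2.0)$, with 6 for $OR \ge 2$. Half-open
intervals close the printed band gaps (1.19 → 1.20 and so on) without
overlap, making the mapping a total function.

Decisions taken where the method description is silent:

* **p-value**: two-sided Wald test on the log-odds coefficient.
* **Age**: continuous in years (calendar year − birth year), linear.
* **Degenerate categories** (no users, no outcome variation, collinear):
  weight 0 with a warning rather than dropping the year, so the weight
  table stays total.
* **Calibration population**: person-years observed at a pharmacy.
  Non-index-only fillers enter with all-zero category indicators; pure
  non-fillers are excluded (their vital status cannot be conditioned on a
  fill).
* Persons who die or emigrate during year $t$ are excluded — death in
  $t+1$ is not defined for them.

### Scoring

$R_{i,t} = \sum_c w_c(t)\, X_{ic}$ over *distinct* categories (fill counts
are irrelevant; duplicate dispensing rows never change a score). A
person-year with no index fill has a **missing** score. Missingness is a
first-class state at this layer — never coerced to 0 — because downstream
analyses treat it as its own exposure category and probe it in sensitivity
variants. With 46 categories any score lies in $[-46, 276]$; observed
scores are far narrower because few categories are filled jointly.

## 2. The cohort

Follow-up is an open cohort over calendar years 2006–2017. A person enters
on January 1 of `max(2006, year turning 51)` and exits at the earliest of
first hip fracture, death, emigration, or December 31, 2017. Persons with
any fracture in the 1994–2005 look-back window are excluded entirely
(`apply_washout()`), so remaining events are first fractures; persons never
filling a prescription during 2005–2016 are not part of the population at
risk (`require_any_dispensing()`).

Each person-year becomes one **exposure slice** carrying the *previous*
year's score (`R_{i,t-1}`), banded as ≤0, 1–5, 6–10, 11–15, 16–20, 21–25,
>25, or missing. Numerical conventions, with month as the finest date
resolution available:

* An event or censoring in month $m$ contributes $m/12$ person-years — the
  event month counts as time at risk. Person-time is conserved exactly:
  the slice total per person equals the entry-to-exit month difference,
  which the tests verify against an independent date oracle.
* Fracture and death in the same month: the fracture is counted.
* Entry is at the calendar-year level (January 1 of the year turning 51),
  not the birthday.
* A person at risk before their first score year keeps the missing band
  rather than being excluded.

## 3. Rates and models

### Standardized rates

`standardized_rates()` directly standardizes on birth year × calendar
year: for a target group $g$ (say, women 66–80 in band 6–10),
$\hat r_g = \sum_s w_s (e_{gs}/y_{gs})$ scaled to 10,000 person-years,
with $w_s$ the standard distribution. The default standard is the whole
supplied cohort's person-time distribution over those strata — the method
description names no standard, so this choice is declared and
configurable. CIs use the normal approximation with Poisson stratum
variances, $\operatorname{Var} = \sum_s w_s^2 e_{gs}/y_{gs}^2$; strata
with no person-time in the target are skipped with renormalized weights
(exact Poisson intervals would be preferable for very sparse strata; the
normal form is used because the headline strata are large).

### Negative-binomial IRRs

Counts aggregated over sex × birth year × calendar year × band are
modelled as negative binomial with quadratic variance
$\mu(1 + \alpha\mu)$, log link, and offset $\log(\text{person-years})$ —
the parameterization in which the overdispersion estimate is the familiar
"alpha". Fits use `MASS::glm.nb`; $\alpha = 1/\theta$, with a delta-method
CI on the log scale. When data are equidispersed the $\theta$ iteration
diverges; the implementation detects this and returns the Poisson limit
with $\alpha = 0$, which also covers saturated micro-examples such as the
two-cell crude-ratio check. Adjustment for birth year and calendar year is
continuous-linear by default with a factor parameterization available —
the published analyses do not state which was used, so both are offered.
The missing band is kept as its own indicator in all main fits. Wald 95%
CIs are reported throughout; the reference band (≤0) is pinned at exactly
1.

Other estimators follow the same pattern:

* `fit_trend_irr()` — the lagged score as a continuous covariate, on cells
  aggregated by exact score value; missing scores excluded.
* `test_interaction()` — likelihood-ratio test of band × modifier product
  terms; if the NB fit collapses to the Poisson limit for either model,
  both are refit as Poisson so the likelihoods are comparable.
* `sex_contrast()` — women-vs-men IRR within band × age-group strata.
* `category_irr()` — person-level fit of all category indicators of one
  exposure year against fractures in the following year, offset by the
  outcome-year person-time, adjusted for birth year (and sex when pooled).
* `latency_analysis()` — band IRRs with exposure fixed 1, 3 or 5 years
  before the outcome year; scores above 15 collapse into one band because
  single-year outcomes leave few events in the top bands. Persons who
  fracture, die or emigrate between the exposure and outcome year are
  excluded from that lag's risk set (a declared choice; the source
  methodology does not state it).
* `sensitivity_variants()` — missing-score slices of under-70s moved to
  the reference band, or missing slices dropped, then the main fit.

## 4. The synthetic registry

`simulate_population()` exists so that calibration, scoring, cohort
construction and the models can all be tested by parameter recovery. Per
person: sex, a baseline age uniform on 50–95 (populating all three
attained-age groups), and a standard-normal frailty scaled by
`frailty_sd`. Year by year:

* Each category is filled independently with logit-linear probability in
  frailty and age; a shared frailty is the simplest structure that induces
  realistic within-person correlation of categories across years. With
  probability `nonfiller_rate` (default 0.14, matching the reported ~86%
  of the population filling an index medication per year) the person-year
  has no index fill; fillers are guaranteed at least one category.
* Death in year $t+1$ is Bernoulli, logit-linear in the year-$t$ category
  indicators (log of the true ORs), sex and age. Default baseline: 3%
  annual odds at age 70, rising ~9% per year of age.
* The first fracture in year $t+1$ has a constant within-year hazard,
  log-linear in the year-$t$ true score (default rate ratio 1.07 per
  unit), age (+8%/year) and sex (×1.5 for women), with baseline 30 per
  10,000 person-years at age 70 — magnitudes chosen once to sit in the
  range a fracture epidemiologist would call realistic for this age span.
  Fracture months are uniform within the at-risk months of the year.
* Emigration (default 0.2%/year) and a pre-2006 fracture history (default
  2%) generate censoring and washout exclusions.

The "true" score uses the weight the step function would assign to each
category's generating OR (p ≈ 0 for non-null ORs, p = 1 for OR exactly 1);
default ORs sit near band centres so calibration noise rarely crosses a
band edge. `persistent_fills = TRUE` freezes each person's category set
after the first year, giving a zero-drift score used to test that latency
attenuation vanishes when there is nothing to attenuate.

What the generator does **not** emulate: real Norwegian drug-utilization
frequencies per ATC code, institutionalization (dispensings unobserved
while fracture risk persists), multi-indication drugs, seasonal
dispensing, or any empirical joint distribution of categories. Passing
recovery tests therefore show that the *pipeline* is correct under its own
assumptions, not that real-registry estimates would be reproduced.

## 5. Problem sizes and seeds in the test suite

Simulation-backed tests use 20,000 persons over 2005–2016 for the shared
fixture, 100,000 for the person-time-conservation audit, 40,000 for the
latency properties, and 20 seeded replicates of 30,000 for end-to-end
recovery of the per-unit fracture rate ratio (the recovery check asks the
95% CI to cover the generating value in at least 18 of 20 replicates).
These sizes keep the whole suite within a few minutes while leaving
Monte-Carlo error well below the effect sizes being checked; stochastic
assertions use explicit standard-error-based tolerances rather than fixed
fudge factors. All randomness flows through the generator's single seed;
estimation stages are deterministic.

## 6. Known limitations

* The packaged mapping is a structural reconstruction (see §1).
* Weight calibration treats deaths as the only outcome; the original
  index's external mortality validation is out of scope.
* Rate CIs use normal approximations; very sparse strata (the >25 band in
  small simulations) produce wide or degenerate intervals.
* Negative-binomial dispersion CIs come from the observed information for
  $\theta$; profile intervals are not implemented.
* Month-level dates make person-time exact only to 1/12 year, and the
  event-month convention (full month counted) is one of several
  defensible choices.
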