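---
title: "Rating the patient impact of medicine shortages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating the patient impact of medicine shortages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortageimpact)
```

## The problem and the model

Counting medicine shortages treats every shortage as equally bad. In
practice a temporary gap in a multi-source oral generic with a drop-in
substitute and a months-long gap in a hospital oncology injectable without
any licensed alternative are very different events for patients. This
package implements an ordinal multi-criteria framework for rating the
patient impact of a shortage at the moment it starts, built around five
elements:

* **Alternative product** — how disruptive the proposed solution is,
  following the pharmacy-practice preference ladder: generic substitution,
  therapeutic substitution, unlicensed product (pharmacy preparation or
  import), or no suitable therapy at all.
* **Disease** — severity of the condition the product treats, graded
  through WHO disability weights or a mild/moderate/severe enumerant.
* **Susceptibility** — two aspects: *vulnerability* of the treated
  population (age range from the leaflet) and *trust* in the alternative
  therapy (patient-contact notes, media attention, patient-forum reports).
* **Costs** — two aspects: the *medicine cost* of the alternative relative
  to the product in shortage, and the *personnel cost* of the extra work
  the switch creates.
* **Number of patients affected** — prior-year users, with conventions for
  hospital products (moderate by default) and orphan indications (low).

Each element is rated 1 (low), 2 (moderate) or 3 (high). An element with
several aspects takes the **maximum** of its aspect ratings; only the
ordering 1 < 2 < 3 is ever used. The five ratings are **multiplied** into
an overall score in 1–243 (= 3^5). Multiplication, rather than summation
(which would compress the scale to 5–15), sharply separates shortages that
rate high on several elements; the additive variant is available via
`overall_score(method = "sum")` for sensitivity analysis. All five
elements are weighted equally.

The elements trace back to the three outcome families of the ECHO
(economic, clinical, humanistic outcomes) model, again by the max rule:

* economic = max(costs, number of patients),
* clinical = max(disease, alternative product [primary aspects],
  vulnerability),
* humanistic = max(alternative product [secondary aspects], trust).

Two classification flags summarise the pattern: *direct* high impact
(alternative product or disease rated 3) versus *indirect* high impact
(costs, susceptibility or number of patients rated 3), and the
*unforgiving* flag for shortages rating high on at least two elements
(`classify_unforgiving()`, `k = 2` by default) — those where a missed dose
cannot be absorbed and mitigation must be prompt.

## Registry conventions

A shortage is an authorised product nationally unavailable for **at least
two weeks**; shorter gaps are usually buffered by stock in the chain.
Duration is counted inclusively on both ends, so an episode starting 1 Jan
and resolved 14 Jan is eligible. Episodes with no end date are ongoing and
**retained**, because the framework rates impact at the start of a
shortage — how ongoing cases at cut-off should be handled is genuinely
open, and retaining them is the choice that does not condition on the
future. A recurrence within **30 days** of resolution (gap of exactly 30
merges) is the same shortage; `merge_episodes()` applies this rule
pairwise in date order and is idempotent. Parallel imports, homeopathic
and herbal medicines and unregistered products are outside the definition
and dropped when a `product_type` column is present. Registries are
comma-delimited UTF-8 with ISO-8601 dates and empty fields for missing
values.

## Tunable parameters

The framework fixes the scale and the max rule but leaves several numeric
cutpoints open; they live in `rater_config()` so every scored output can
be traced (via `config_fingerprint()`) to the settings that produced it:

| Parameter | Default | Meaning |
|---|---|---|
| `disability_low_max` | 0.10 | weight ≤ this → disease low |
| `disability_high_min` | 0.30 | weight > this → disease high |
| `child_age_max` | 18 y | below: child (vulnerability) |
| `elderly_age_min` | 65 y | above: elderly (vulnerability) |
| `n_patients_low_max` | 1,000 users/y | ≤ this → few patients |
| `n_patients_high_min` | 100,000 users/y | ≥ this → many patients |
| `solution_ladder` | 1/2/2/3 | see below |
| `quartile_method` | type 7 | cost-threshold estimator |

Decisions worth spelling out, because the design was genuinely open:

* **Solution ladder.** `generic_substitution → 1`,
  `therapeutic_substitution → 2`, `unlicensed_product → 2`,
  `no_therapy → 3`. The preference ladder orders the four rungs; the
  calibration that therapeutic substitution and unlicensed products both
  rate moderate — and only the total absence of therapy rates high — is
  consistent with high alternative ratings being very rare (about 1% of
  shortages) while every published highest-impact product carries an
  alternative rating of 2. The ladder is a config entry, not a constant.
* **Disability-weight cutpoints.** WHO weights quantify health loss on
  [0, 1] but no published cutpoints exist for this framework; 0.10/0.30
  put, e.g., mild hearing loss below, and severe depressive episodes
  above, the band. A disease WHO classes at several severities depending
  on progression (`multi_class`) rates moderate.
* **Vulnerability from an age range.** Entirely below `child_age_max` or
  entirely above `elderly_age_min` → 3; including children or elderly
  alongside adults → 2; adults only → 1.
* **Trust from surveillance signals.** Media attention or patient-forum
  reports → 3; notes on patient contact alone → 2; nothing → 1. Whether
  intensity (how much media attention) should matter is unknowable from
  presence/absence registries; the rater uses presence/absence.
* **Cost thresholds are cohort-relative.** The ratio
  100·price_alternative/price_original is rated against the cohort's own
  interquartile range: strictly above q3 → high, strictly below q1 → low,
  boundary values → moderate (the rule speaks of "above" and "below").
  Quartiles use linear interpolation on the sorted sample (R's type 7,
  the default of mainstream statistics software), and the method label
  travels with the thresholds. At least 4 ratios are required; otherwise
  explicit `cost_thresholds()` must be supplied. Note the rule caps the
  high and low medicine-cost shares near 25% *by construction*.
* **Personnel costs equal the alternative-product rating**: the work a
  switch creates for pharmacists and physicians scales with how disruptive
  the switch is. This makes the costs element
  max(medicine cost, alternative rating), so costs can never rate below
  the alternative element.
* **Orphan precedence.** An orphan indication rates the number of
  patients low even for hospital products; the hospital default (moderate)
  applies only when no usage count is available.
* **ECHO aspect fallback.** When only combined element ratings are known
  (as in published tables), the element rating stands in for each of its
  aspect slots. This is an upper-bound convention — it can only raise, not
  lower, the humanistic and clinical outcomes — and is flagged as
  `aspect_fallback` in results.

## Cohort statistics

`required_sample_size()` implements n0 = z²p(1−p)/e² with the exact normal
quantile (1.959964 at 95%, not 1.96) and the finite-population correction
n = n0/(1+(n0−1)/N), rounded up; for N = 1844 at 95%, ±5%, p = 0.5 this
gives 319, and it converges to the uncorrected 385 as N → ∞.
Representativeness of a drawn sample is tested by chi-square
goodness-of-fit of the sample counts against the population proportions —
a subset is not independent of its population, so the goodness-of-fit
formulation is the well-posed one; categories with expected counts below 5
are flagged. Stratified overall scores are summarised by median and
type-7 quartiles (the same estimator as the cost thresholds, for internal
consistency) and compared with the Kruskal–Wallis test plus pairwise Dunn
z-tests on mean pooled ranks with tie correction. The Dunn adjustment
defaults to Bonferroni (Holm and none are available) and the label is
always recorded. Both tests are rank-based, hence invariant under
monotone transformations of the score — which is the right property for a
multiplicative ordinal scale.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` exists so the whole pipeline is testable without a
confidential registry. It emulates:

* the categorical **marginals** of the Dutch 2012–2015 shortage
  population (1844 shortages: year 21.0/23.8/25.5/29.7%, oral 56.7%,
  parenteral 30.0%, ATC class N 18.1%, originator 54.8%, ...);
* the published **element-rating shares** (disease high 29%,
  susceptibility low 79%, alternative moderate 60% / high 1%); cells that
  were never published (the low/moderate splits for disease, the full
  n-patients distribution) are free parameters fixed once at plausible
  values — `c(0.25, 0.46, 0.29)`, `c(0.79, 0.18, 0.03)`,
  `c(0.39, 0.60, 0.01)` and `c(0.30, 0.60, 0.10)`;
* **cost ratios** drawn log-normal with median 100% (sdlog 0.6). Cost
  ratings are *derived*, not target-sampled: the rating is
  cohort-relative, so the generator applies the same quartile rule to its
  own ratio sample, which makes boundary records self-consistent by
  construction. The missing-price share of 0.2 makes the expected
  high-cost share 0.8 × 25% = 20%, the published value.

Each record's raw fields are constructed to **invert** the raters: a
record destined for disease 3 gets a severe indication (or a weight above
0.30), a child-only age range realises vulnerability 3, media attention
realises trust 3, and so on. `recover_ratings_check()` therefore has a
sharp contract — 100% agreement on every element when generator and rater
share a `rater_config` — and a failure is a genuine defect, not noise.

What it does **not** emulate: attributes are sampled independently across
variables (no published joint distribution exists; there is no reason ATC
class and solution category should be independent in reality), durations
carry no information beyond eligibility, and the cohort's overall-score
distribution is whatever the independent marginals imply — at the
defaults its median comes out somewhat above the published Dutch median.
Passing tests on synthetic cohorts therefore demonstrate that the
*machinery* is correct and internally consistent, not that any particular
real cohort's percentages will be reproduced.

## Numerical and degenerate-input choices

Ratings are integers and comparisons exact, so there is no tolerance
anywhere in the scoring path. Quartile estimation is the only
interpolation; its type-7 label is recorded in every thresholds object.
A zero original price makes the cost ratio undefined: the medicine aspect
is omitted with a warning and the personnel aspect stands alone. A record
with no user count that is neither a hospital product nor an orphan
indication is an error, not a guess. Empty cohorts and empty strata are
valid inputs (vacuous outputs, with warnings where a stratum is dropped).
Sampling and generation restore the caller's RNG state.

## Problem sizes used in the shipped analyses

The `analysis/` scripts simulate a population of 1844 (the size of the
Dutch cohort) and rate a drawn sample of 324; the test suite exercises
property checks on all 243 rating combinations, randomized profile sets
of 10^4, and synthetic cohorts up to 10^4 records for marginal-recovery
bounds at three binomial standard errors. These sizes make every
distributional check sharp to well under a percentage point while keeping
the full suite fast.

## Known limitations

* The rating-examples annex that accompanied the original framework is
  not public; edge-case calibrations (the ladder, the cutpoints) are this
  package's own, configurable choices.
* Published p-values of the original cohort's representativeness tests
  cannot be reproduced exactly (the original procedure is not fully
  specified); this package's chi-square variant is documented above.
* The ECHO aspect fallback can overestimate humanistic ratings for data
  with combined element ratings only.
* No currency conversion, no automated WHO disability-weight lookup, no
  registry scraping: attribute values are expected already extracted.
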