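---
title: "Point-based diabetes case finding: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-based diabetes case finding: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscore)
```

## The model

`dmscore` implements a rule-based computable phenotype for diabetes
mellitus that operates on a longitudinal stream of structured EHR events.
Each qualifying event contributes a fractional point value; a patient's
cumulative total classifies them three ways:

* **no diabetes** — total exactly 0;
* **possible diabetes** — total strictly between 0 and 1;
* **diabetes** — total at or above the diagnostic threshold of 1 point.

Because points accumulate chronologically, the model also yields an
*earliest diagnosis date*: the first calendar date on which the running
total reaches the threshold. That makes the phenotype usable in real time —
a registry can flag a patient on the day the evidence becomes sufficient,
rather than retrospectively.

The eight criteria and their default weights are:

| Criterion | Qualifying rule | Settings | Points | Accrual |
|---|---|---|---|---|
| ICD-9 encounter code | 250.xx | inpatient or outpatient | 0.75 | per distinct date |
| Hemoglobin A1c | ≥ 6.5% | inpatient or outpatient | 1.00 | per distinct date |
| Fasting glucose | ≥ 126 mg/dL | outpatient only | 0.50 | per distinct date |
| Random glucose | ≥ 200 mg/dL | outpatient only | 0.50 | per distinct date |
| 2-hour OGTT | ≥ 200 mg/dL | inpatient or outpatient | 0.75 | per distinct date |
| Problem list / PMH | 250.xx | inpatient or outpatient | 0.40 | once per patient |
| Diabetes medication | present | outpatient only | 1.00 | once per patient |
| Metformin | present | outpatient only | 0.75 | once per patient |

The weights mirror ADA diagnostic logic. A single fasting glucose ≥ 126
mg/dL is half of a diagnosis (ADA requires two), so it carries 0.5 points
and two qualifying values on distinct dates cross the threshold on the
second date. A single HbA1c ≥ 6.5% is diagnostic on its own. The
lower-than-1 weights for encounter codes, metformin, and problem-list
entries encode known failure modes of those fields: isolated miscoded
encounters, metformin prescribed for pre-diabetes or polycystic ovarian
syndrome, and stale or inaccurate problem lists would otherwise create
false positives on their own. Sites with more reliable documentation can
reweight via `set_weights()` or a YAML file (`read_weights()`); the
shipped default is in `system.file("extdata", "weights.yaml", package =
"dmscore")`.

## Accrual policy

The central design question for a cumulative scorer is *when the same
criterion may contribute again*. The package's policy, configurable per
criterion:

* **Labs and encounter codes accrue once per criterion per calendar
  date.** Repeat evidence on new dates is genuinely new information — two
  fasting glucoses a month apart are the ADA's two-test confirmation, and
  two dated 250.xx encounters (0.75 + 0.75) are diagnostic, consistent
  with the widely used two-code claims standard. Duplicate draws of the
  same test on one day, or multiple 250.xx codes on one visit, are one
  piece of evidence and count once.
* **History entries, diabetes medications and metformin accrue once per
  patient.** A medication refill or a re-entered problem-list line
  duplicates the same underlying fact. Were metformin allowed to accrue
  per date, two refills (1.5 points) would re-create exactly the
  pre-diabetes/PCOS false positives its 0.75 weight exists to avoid.
* **Different lab kinds on the same day each count** — a same-day fasting
  glucose and HbA1c are independent diagnostic evidence.

"Outpatient only" excludes both inpatient and emergency/urgent settings
for the glucose and medication criteria: stress hyperglycemia and
inpatient sliding-scale insulin are the confounds the restriction targets,
and the emergency department shares them. This is configurable via each
criterion's `allowed_settings`.

All point arithmetic is carried out in integer centipoints (every shipped
weight is a multiple of 0.05), so the threshold comparison at exactly 1.00
point is exact — no floating-point tolerance is involved, and sums like
0.5 + 0.25 + 0.25 cannot miss the boundary.

Same-date events are order-independent by construction: contributions are
keyed by (criterion, date), so permuting a day's rows never changes the
total, the category, or the diagnosis date. These invariants — plus
monotonicity (more evidence never lowers a total or delays a date) and
agreement of the streaming date with brute-force evaluation over all
date-prefixes — are asserted property-style in the test suite.

## The claims comparator

`claims_two_code()` implements the claims-based baseline: a patient is
identified when 250-category encounter codes appear on two distinct
calendar dates (any care setting), and the diagnosis date is the second
such date. Same-date codes deduplicate by default ("two encounters" means
two claims), controllable via `dedup_same_date`. Lab-only diabetics are
structurally invisible to this rule — the synthetic `true_diabetic_labs`
archetype exercises exactly that gap.

## Validation statistics

`validate_scores()` assembles, against gold-standard labels:

* the 3×3 agreement table over none/possible/diabetes, with Cohen's kappa,
  unweighted and linear-weighted (`w_ij = 1 − |i−j|/(k−1)`; on 2×2 tables
  the two coincide, which the tests assert);
* binary metrics under both dichotomisations of the "possible" group
  (combined with the negatives — the primary analysis — and with the
  positives). PPV and NPV are computed on the cohort as supplied; when
  that cohort was enriched by stratified sampling they are inflated
  relative to the source population and should be read as
  cohort-conditional;
* an ROC sweep over point thresholds (predict positive iff total ≥ t),
  with the C statistic computed by the trapezoidal rule over the curve
  augmented with (0,0) and (1,1). The tests cross-check it against the
  tie-corrected Mann–Whitney estimate and an independent ROC
  implementation;
* diagnosis-date agreement for patients diagnosed by both model and gold:
  exact matches and matches within a window. "3 months" is implemented as
  **92 days** by default (the longest 3-calendar-month span;
  calendar-month arithmetic is locale-fragile), symmetric by default with
  a one-sided `model_late` mode in which the model may only lag the gold
  date; both readings are reported. A quarter-bin kappa on the two dates
  is also reported, clearly a *reconstruction*: published date-kappa
  figures for this kind of model do not define their categories, so we do
  not attempt to reproduce them. Point estimates only; no bootstrap
  intervals.

Degenerate inputs are reported as undefined rather than coerced: a metric
with a zero denominator is `NA`, kappa with expected agreement 1 is `NA`,
and an ROC requires both classes.

## The synthetic cohort generator

No real patient data ships with (or is usable by) this package, so
`generate_cohort()` produces cohorts in which the truth is known by
construction. Nine archetypes cover the three evidence routes to true
diabetes (repeat qualifying labs, a diabetes-medication order, repeat
encounter codes) and the documented noise modes (metformin for
pre-diabetes, metformin for PCOS, a stale problem-list entry, an isolated
miscoded 250.xx encounter), plus healthy and healthy-elderly controls.
Each diabetic's gold date is defined as the earliest date the generated
chart satisfies the archetype's diagnostic evidence (e.g. the second
qualifying glucose), so earliest-date recovery is exactly checkable:
on noise-free mixes the scorer attains sensitivity = specificity = 1 with
100% exact date agreement, and restoring the pre-recalibration weights
(metformin or encounter codes at 1.0) measurably lowers specificity —
both asserted in tests.

Generator conveniences, not clinical claims: background event counts are
Poisson with mean 6.6 per patient (a typical outpatient encounter count
for such cohorts); diabetic HbA1c values are lognormal centred near 8%,
non-diabetic values uniform on 5.0–5.6%; glucoses analogous; the
observation window spans 27 months. What the generator does **not**
emulate: realistic ICD-9 code diversity beyond 250.xx and a small
distractor set, comorbidity structure, visit-level clinical realism,
missingness patterns, or units heterogeneity. Passing tests on synthetic
cohorts therefore demonstrate the *algorithmic* contracts (weights,
accrual, dates, statistics), not field performance on real EHR extracts.

Randomness is fully seeded: each patient draws from a substream derived
from `(seed, patient index)`, so cohorts are byte-identical across runs
and the first *n* patients are stable when the cohort grows.
`stratified_sample()` reproduces the chart-review designs (50/25/25
derivation and 50/10/40 validation fractions, "up to n" semantics with a
warning on short strata), and `age_restrict()` applies the ≥ 50-year
restriction to the negative stratum only, inclusively at the boundary.

## Problem sizes and numerical choices

The test suite runs at sizes chosen to exercise the contracts thoroughly
while staying quick on a laptop: 1,000 randomized timelines for the
prefix-date oracle, a 500-patient noise-free cohort for perfect recovery,
a 400-patient noisy cohort for the reweighting analyses, and 500+ random
tables/score sets for the statistics. Ties in ROC thresholds are handled
by sweeping the distinct observed totals; `>=` comparisons make boundary
lab values (6.5%, 126, 200 mg/dL) qualify. ICD-9 matching is
category-level: `250`, `250.0`, `250.00` qualify, a dotless `2500` does
not.

## Known limitations

The model does not distinguish type 1, type 2 and secondary diabetes; it
cannot separate incident from prevalent disease in systems whose records
begin mid-history; and its weights are site-calibrated — systems with more
accurate problem lists should consider raising that weight. The package
reports predictive values without prevalence correction, and the
validation statistics here are only as good as the gold labels supplied.
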