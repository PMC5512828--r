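---
title: "Total CVD risk assessment, treatment concordance and documentation accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total CVD risk assessment, treatment concordance and documentation accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penrisk)
```

## The problem

Primary-care programmes for non-communicable diseases in low-resource and
humanitarian settings increasingly manage cardiovascular prevention through
*total* CVD risk: treatment decisions are anchored to a patient's absolute
10-year risk of a cardiovascular event, estimated from sex, age, smoking,
diabetes, systolic blood pressure (SBP) and total cholesterol (TC), rather
than to any single risk factor. The WHO Package of Essential NCD
interventions (WHO PEN) operationalises this with the WHO/ISH risk charts:
colour-banded lookup tables, published per epidemiological subregion, that
map the six factors onto five ordered risk strata (`<10`, `10-<20`,
`20-<30`, `30-<40`, `>=40` percent).

Evaluating such a programme from routine electronic records raises a set of
recurring, fiddly methodological questions: who should have been risk
assessed, which of a patient's many measurements should feed each analysis,
what to do about missing laboratory values, who was eligible for
lipid-lowering treatment (LLT), and whether the risk scores clinicians
wrote in the chart agree with what the recorded risk factors imply. penrisk
packages that entire quantitative workflow — together with a calibrated
synthetic cohort generator, because clinical databases of this kind are
rarely shareable.

## The data model

A cohort is relational: a `patients` table (demographics, a controlled
vocabulary of condition codes, risk-factor fields), visit-stamped
`measurements` (SBP in mmHg, TC in mmol/L; a missing value is a recorded
absence, not a dropped row), `prescriptions` (`lipid_lowering` vs `other`)
and clinician-`documented_scores`. Measurements and prescriptions may
predate enrolment; ages are integer years at enrolment (the source systems
store age, not date of birth, so no date arithmetic is attempted).

A previous history of CVD is coded positive on any of: stable or unstable
angina, myocardial infarction, angioplasty, congestive heart failure,
peripheral vascular disease, any other CVD condition (e.g. atrial
fibrillation), or a documented cardiovascular/cerebrovascular complication.
Site-specific source strings are translated through a user-editable YAML
mapping; codes outside the vocabulary are ignored with a warning.

## Cohort inclusion

Screening follows the WHO PEN Protocol-1-derived rule: everyone aged 40 or
over; adults 18–39 only with a qualifying risk factor (current smoking or
quit within 12 months, diabetes of either type, family history of
premature CVD or of diabetes in a first/second-degree relative, or high
waist circumference — at least 90 cm in women, 100 cm in men, inclusive).
Children are never included.

Two deliberate conventions where the underlying procedure is silent:
missing risk-factor fields (including waist circumference) count as
*absent* risk factors, so an under-40 patient with missing waist can only
qualify through the other criteria; and both diabetes types count as
"diabetic" everywhere a rule says diabetic.

## Chart scoring

`calculate_risk()` is a pure banded table lookup. All band edges are
half-open and lower-inclusive — SBP 140.0 falls in `140-159`, TC 8.0 in
`>=8` — so extreme values (SBP 210, age 93) are always scoreable. Two
conventions to note:

* **Ages 18–39 are scored on the lowest (40-year) chart band.** The
  published charts start at 40, but screening admits qualifying adults
  from 18. This is a package convention, documented here, not a WHO
  statement.
* **The shipped chart is synthetic.** The licensed WHO/ISH cell values are
  not redistributed; `synthetic_chart()` builds a complete 640-cell chart
  from a simple monotone 10-year-hazard model evaluated at band midpoints
  (risk increases with age, SBP, TC, smoking, diabetes and male sex), cut
  at 10/20/30/40%. Every numerical claim the package's tests make about
  population data is independent of specific cell values; a transcription
  of a real subregion chart in the same CSV layout can be supplied through
  `load_chart()`, which enforces completeness (missing, duplicate or
  invalid cells are hard errors).

## Index dates, measurement selection and imputation

Three analyses use three anchors:

| analysis | index date | selection |
|---|---|---|
| population risk profile | enrolment | first value on/after the index |
| treatment eligibility (treated) | first LLT prescription | most recent value strictly before |
| documented-score accuracy | first documented score | most recent value strictly before |

Never-treated patients keep their enrolment profile for eligibility.
"Strictly before" is a deliberate reading of "prior to": a same-day
laboratory result may postdate the clinical decision, so it is excluded by
default (`retrospective_strict = FALSE` relaxes this). Same-date ties
resolve to the first record in file order, with a warning.

Missingness is handled as in the source programme: absent SBP is filled
with a constant (`sbp_fill_mmHg`, default 130 — an admission mean in a
setting where SBP missingness was ~0.5%), and absent TC by ordinary least
squares on the complete cases with three predictors — age, sex and SBP.
SBP imputation necessarily precedes the TC model (SBP is a predictor), the
model is fitted once on the enrolment-profile complete cases and reused in
every context, and imputation never alters an observed value (flags mark
exactly the filled entries). The sex indicator codes female = 1; any
full-rank coding predicts identically.

## Treatment eligibility and concordance

WHO PEN makes four groups eligible for lipid-lowering treatment: existing
CVD (secondary prevention), diabetics aged ≥ 40, TC ≥ 8 mmol/L, and chart
risk ≥ 20%. `assign_category()` applies these as *mutually exclusive*
categories in that precedence order, so the categories partition the
cohort; the residual `risk_lt20` group is not eligible. The TC used by the
≥ 8 rule is the same selected/imputed TC used for scoring in the same
context, and the age is age at enrolment. `concordance()` then tabulates
per-category prescribing with binomial confidence intervals plus the
overall prescribed-given-eligible proportion.

## Documented-versus-calculated agreement

For each patient with a documented score, the first documented category is
paired with the recalculated one; patients with existing CVD appear on the
calculated side as their own `history_of_cvd` level, since a chart score
is undefined for secondary prevention. The analysis reports:

* the full 5 × 6 cross-tab and its diagonal share ("documented correct");
* the 2 × 2 aggregation at the clinically significant 20% threshold,
  with CVD counted as high risk;
* Cohen's kappa, κ = (p₀ − pₑ)/(1 − pₑ), in two variants. The *match
  rule* — a CVD patient documented ≥ 20% is coded as a match — rewrites
  the calculated side of such pairs to the documented category before the
  six-level kappa; the residual `history_of_cvd` column (CVD patients
  documented < 20%) is retained as a sixth category with an empty
  documented margin. Both the 2 × 2 kappa and the six-level matched kappa
  are reported because the aggregate construction materially changes the
  statistic (≈ 0.166 vs ≈ 0.178 on the reference tables below). Kappa
  significance testing is deliberately omitted.

Confidence intervals default to the Wilson score interval with continuity
correction, which reproduces the reference report's printed bounds for
small counts (e.g. 12.4–68.4% for 4/11); Clopper–Pearson (`"exact"`) is
also provided, since other printed intervals (e.g. 0.09–0.45 for 6/25)
follow that convention. The method used is recorded per report.

## The synthetic cohort generator

`default_spec()` encodes the published per-stratum marginals of a refugee
primary-care NCD cohort from the Eastern Mediterranean region (the
`reference_tables()` aggregates): stratum mix (20.9% existing CVD, 56.8%
latent `<10`, …), per-stratum age medians/IQRs, percent male, diabetes and
smoking prevalences, SBP/TC means and sds, 576/2907 TC and 15/2907 SBP
missingness, a 680/2907 documentation rate, and per-category prescribing
probabilities (0.706 for CVD history, 0.374 for diabetics ≥ 40, 0.636 for
TC ≥ 8, 0.167/0.163 above/below the 20% threshold).

Distributional choices where only summaries are published: ages are
log-normal matched to the printed median/IQR; SBP and TC are Gaussian with
the printed stratum moments, clamped to physiologic bounds (70–260 mmHg,
2–15 mmol/L); risk factors are conditionally independent given the
stratum, because within-stratum correlations are not published — cohorts
generated here will therefore understate any real risk-factor clustering.
The documentation error process draws the documented category from a
6 × 5 kernel, P(documented | true), whose default is the column-normalised
reference agreement table — i.e. the empirically observed under-calling, in
which 91% of CVD patients' documented scores are `<10`. The kernel is
fully configurable (an identity kernel produces error-free documentation).

Two things the generator does *not* emulate: longitudinal visit dynamics
(each patient gets baseline measurements and at most one follow-up per
kind) and provider behaviour (prescribing depends only on the true
eligibility category). Passing pipeline tests on synthetic cohorts
therefore demonstrates the *method* — selection, imputation, scoring,
classification and tabulation — not the realism of any particular clinic.

Latent stratum labels, not chart outputs, define the generator's truth:
realised chart scores depend on the chart supplied, so calibration tests
compare against `truth_table()`.

## Numerical and testing choices

* Quantiles use the default order-statistic definition with linear
  interpolation.
* Chart lookup hard-errors on any missing cell, naming it; `load_chart()`
  refuses incomplete files outright.
* Kappa returns `NA` with a warning when expected agreement is 1.
* Empty eligibility categories and empty agreement tables are emitted
  (flagged) rather than dropped.
* Reported problem sizes: unit tests run on cohorts of a few hundred;
  calibration-recovery tests use n = 10,000 with 50 seeded replicates,
  checking that the pipeline's 95% CIs cover the generator's prescribing
  probabilities in at least 90% of replicates — sizes chosen so binomial
  error is a few tenths of a percentage point while a full run stays in
  the order of a minute.

## A worked run

```{r example}
spec <- default_spec(n_patients = 2907, seed = 20151101)
cohort <- generate_cohort(spec)
report <- run_pipeline(cohort, chart = synthetic_chart())
report
```

## Known limitations

The chart is synthetic (see above); prescribing is not adherence, and no
attempt is made to model refusal of offered treatment; the documented-score
analysis conditions on documentation existing, so it says nothing about
*why* 3 in 4 scores were never documented; and gender-stratified analyses
are out of scope.
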