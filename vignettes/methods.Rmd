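---
title: "Methods: comparing telemonitored and surgery blood pressure in routine data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing telemonitored and surgery blood pressure in routine data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telebp)
```

## The estimation problem

When a telemonitoring service is rolled out in routine primary care rather
than trialled, the patients who use it choose (or are chosen) to do so.
Their home readings must be compared with clinic ("surgery") readings from
non-participating patients in the same practices, and every ingredient of
that comparison is biased in a known direction: enrolment is confounded
with age, deprivation and BP control; clinic readings run higher than home
readings (white-coat effect, conventionally ~5 mmHg); home readings arrive
weekly while clinic readings arrive a few times a year, so change is far
easier to see in one group; clinicians round recorded values to preferred
end digits (especially double zeros) much more than home devices do;
patients with higher BP are more likely to stop telemonitoring; and single
readings carry substantial measurement error.

No single estimator fixes all of this, so the package implements four that
fail differently, plus a generator that manufactures cohorts with these
mechanisms switched on or off so each estimator's behaviour is checkable
against a known truth.

## Data reduction shared by three of the methods

`build_standardised_dataset()` reduces each patient to two readings. The
index reading is the *second* telemonitored reading for telemonitoring
patients (the first may have been a test of the system) and the first
surgery reading on/after the service start date (2015-09-01 by default) for
comparators — historical pre-rollout readings would import secular trends.
The final reading is the same-source reading 183–365 days later closest to
day 365 (the "6–12 months" window made day-exact: 6 months ≈ 182.5 rounded
up, 12 months = 365; a tie in distance to day 365 goes to the later
reading, though inside this window ties cannot actually occur). Patients
additionally need a full *potential* year of follow-up: index date + 365 ≤
the extract's observation end. Differences are baseline − final, so
positive values are improvements. The attrition at each step is reported
(`flow_report()`) and is monotone by construction.

## The four estimators

**Standardisation with stratification.** Raised-BP prevalences at 135+,
140+, 145+, 150+ mmHg systolic (85+/90+ diastolic) at index and follow-up
give each group a relative risk reduction RRR = 1 − p_follow/p_base. The
groups are compared by the ratio of RRRs, with a non-parametric bootstrap
percentile interval: patients are resampled with replacement within each
group (the resampling unit is the patient with their paired indicators —
realised internally as a multinomial draw over the four indicator cells,
which is exactly equivalent), the ratio recomputed per resample, and the
2.5th/97.5th order statistics taken; 9999 resamples by default, undefined
resamples redrawn and counted. Comparing the telemonitoring RRR at 145+
against the comparator RRR at 150+ is the white-coat-shifted variant of
the same comparison. The model-based arm (`stratified_lmm()`) subtracts
the white-coat delta from comparator readings, stratifies on (adjusted)
baseline SBP rather than modelling it — regressing change on the initial
value is itself a bias — and fits `difference ~ group + SIMD5+ + sex + age`
with a practice random intercept.

**Standardisation with matching** (`find_matches()`, `paired_t_test()`,
`sensitivity_grid()`). Greedy deterministic 1:1 matching on exact SIMD
decile, sex, age decade and index SBP on a grid (nearest value ending in 0
or 5 by default), after reducing comparator values by the delta; among
eligible comparators the one with the closest final-reading date wins. The
paired t-test on final BP needs no further covariate adjustment (the pairs
carry it) and no practice effect (its variance estimate is zero in data of
this shape). The nine-setting sensitivity grid varies the grid and delta
because the result is genuinely sensitive to the white-coat assumption.

**Regression adjustment for propensity score** (`fit_propensity()`,
`ps_adjusted_lmm()`). A logistic model of enrolment on SIMD 5+, sex, age
and baseline SBP yields fitted probabilities; final SBP is then modelled as
`group + score` with a practice random intercept. The score enters as a
single continuous linear term. Overlap is diagnosed, never trimmed.

**Random-coefficient modelling** (`prepare_longitudinal()`,
`fit_practice_rcm()`, `pool_practices()`). All readings after the cutoff
enter; each patient's first telemonitored reading is deleted; the patient
clock starts at the first retained reading (one clock per patient across
sources). The model per practice is
`bp ~ patient_time * group_code + prior-reading category (0/1–4/5+) +
age + SIMD5+ + sex` with correlated random intercept and slope per patient
(unstructured 2×2 covariance), fitted by REML (`reml = FALSE` for ML). The
time × group(2 vs 0) interaction is the estimand, in mmHg/week; the group
main effect absorbs level differences, which is why this method needs no
white-coat assumption (provided the effect is constant over time).
Per-practice estimates are pooled with the DerSimonian–Laird moment
estimator and a Wald CI (z = 1.96, no small-sample adjustment); the
overall model on pooled rows trades the practice adjustment for one fit.
The surgery-vs-surgery contrast (group 1 vs 0) is computed but flagged
`caution`: transcription of home readings into practice systems
contaminates it.

## Tunable parameters that matter

* `white_coat_delta` (mmHg, default 5, sensitivity 7/10): subtracted from
  comparator surgery values. In the stratified method it cancels in the
  difference outcome and only moves stratum membership; in the matched and
  propensity methods it shifts the estimate one-for-one.
* `adjust_scope` in `stratified_lmm()` (`"both"`, `"baseline"`, `"final"`):
  where the delta is applied is ambiguous in routine practice; `"both"` is
  the default.
* Final-reading window `c(183, 365)` days and the full-year rule.
* `n_resamples` (default 9999) and the matching grid/tie rules
  (`grid_sbp()`: nearest-5 exact for integers; nearest-10 distance-5 ties
  round up).
* `weeks_per_year = 365.25/7 ≈ 52.18` in `annualise()` (52 available).

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: demographics (age ~ N(68, 12²)
truncated to 18–90, 53% female, SIMD weighted towards affluent deciles); a
latent linear systolic trajectory `intercept + slope·t` with intercept ~
N(140, 12²) mmHg and slope ~ N(−0.07, 0.05²) mmHg/week; enrolment by a
logistic model on age, SIMD and latent baseline (log-odds −2.35 − 0.06·(age
− 65) + 0.20·(SIMD − 5.5) − 0.01·(BP − 140), ~10% enrolled); an additional
slope of `intervention_slope_effect` (−0.065/week) for enrolled patients
from their entry date. Readings are Poisson processes (telemonitored
1/week from enrolment; surgery 4/year from 52 weeks before enrolment, so
the prior-reading covariate has something to count), each reading = latent
value + 5 mmHg if surgery-sourced + N(0, 11²) error, then rounded to the
nearest 10/5/nothing with source-specific probabilities — one draw applied
jointly to systolic and diastolic, which is what produces double-zero
preference — then truncated to integer. Diastolic is 0.6 × systolic +
N(0, 6²). Telemonitoring patients withdraw with weekly hazard
0.001·exp(0.02·(latent − 140)); no readings after the dropout week. The
published study reports the dropout *direction* but no quantitative model,
so the log-hazard form and its two constants are this package's choice.

The variance split (between-patient 12, within 11 mmHg) and the drift
(−0.07/week) are calibrated to the published cohort's printed index-BP SDs
(~16–18) and mean one-year declines (~3.5 mmHg comparator, ~6.5
telemonitoring); the selection coefficients target the published age
(~63 vs ~69) and deprivation gaps; the rounding probabilities target ~11%
double zeros in surgery and ~2% in telemonitored readings. These are
calibration aids, not assertions.

What the generator deliberately does **not** emulate: transcription of
home readings into practice systems (so the group-1-vs-0 contrast is clean
here but not in real data); medication titration dynamics; non-linear
trajectories (the analysis models assume linearity, and so does the
generator — passing recovery tests says nothing about curvature bias);
practice-level BP effects (practices differ only by sampling, so τ² ≈ 0 in
simulated pooling); and calendar-time secular trends. Regression to the
mean is not a separate switch — it emerges when groups are assigned on
noisy baselines (`selection_noise_sd > 0`).

## Numerical and design choices

* "Before 1 Sept 2015" is strict: readings dated exactly on the start date
  are kept.
* Age is approximate (reference year − year of birth); the matching decade
  uses age at the index reading's calendar year, model covariates use age
  in 2015.
* A reading violating several plausibility rules is tagged with the first
  rule in the documented order (`verbose = TRUE` lists all); duplicates are
  retained with a warning — routine extracts legitimately contain repeated
  identical readings.
* Mixed models use lme4 with singular (zero-variance-boundary) fits
  accepted and flagged rather than errored, Wald normal CIs and p-values
  for fixed effects, and an automatic fixed-effects-only fallback when a
  grouping factor has one level (single-practice data), which reproduces
  OLS exactly.
* Bootstrap CI endpoints are order statistics (⌊0.025(B+1)⌋ and
  ⌈0.975(B+1)⌉); more than 50% undefined resamples aborts.
* The DL pool truncates τ² at zero, reducing to the fixed-effect estimate
  when Q ≤ k − 1; k = 1 passes the single study through.
* Greedy matching order (ascending index date, then patient id) and all
  tie-breaks are total, so matching is deterministic; "closest in time"
  compares final-reading dates by default (`time_match = "index"` for the
  alternative reading of that rule).

## Validation design and problem sizes

The test suite validates operating characteristics on simulated cohorts at
sizes chosen to make the whole suite run in minutes on one core: type-I
error of all four methods over 200 null replicates of 400 patients
(enrolment unconfounded, no effect, white-coat delta correctly specified,
no withdrawal, 0.5 telemonitored readings/week over ~16 months); slope
recovery over 100 replicates of 800 patients in 8 practices with
confounded enrolment (~25% enrolled); bootstrap coverage over 500
replicate cohorts standardising to roughly 400 vs 3500 patients, with 999
resamples per interval and the population ratio estimated from indicators
pooled across all replicates. Unit-level oracles include an independent
brute-force matcher on 500 small instances, `stats::t.test` for the paired
analysis, hand-evaluated DerSimonian–Laird examples, and `metafor::rma`
as a cross-check of the pooling.

## Known limitations

* The propensity-score method's test is **conservative**: conditioning on
  an *estimated* propensity score balances away chance covariate imbalance,
  so the estimator's true sampling variance is close to that of full
  covariate adjustment while the naive model SE reflects the much larger
  unadjusted residual variance. Its type-I error runs below nominal
  (harmless for confirmation, costly for power).
* With noisily measured confounders (selection acting on the latent BP
  while the model sees a noisy reading), no propensity specification is
  correct and residual confounding survives all standardised-data methods.
* Informative (BP-dependent) withdrawal biases the random-coefficient
  slope contrast slightly away from the truth even under
  missing-at-random-style fitting; the recovery experiments therefore
  switch dropout off to isolate estimator bias, and the dropout mechanism
  is validated directionally (dropouts have higher latent baselines).
* All methods assume linear within-patient BP change, constant white-coat
  effect over time, and no transcription contamination.
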