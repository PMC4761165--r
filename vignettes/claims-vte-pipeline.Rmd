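---
title: "Identifying and quantifying venous thromboembolism in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying venous thromboembolism in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteclaims)
```

## The problem

National insurance claims databases record every reimbursed service —
drug deliveries, imaging exams, hospital stays — but in community care they
carry **no diagnosis**. Only hospital stays are diagnosis-coded, through the
ICD-10 codes attached to the stay's diagnosis-related group (primary and
associated diagnoses). Estimating the incidence of venous thromboembolism
(VTE) from such data therefore needs two different instruments:

* **hospital capture**: a stay qualifies if any of its ICD-10 codes falls in
  the VTE code set — `I80.1`–`I80.9`, `I82.1`–`I82.9` for deep vein
  thrombosis (DVT), `I26.0`, `I26.9` for pulmonary embolism (PE);
* **a temporal phenotyping algorithm** for DVT treated entirely in the
  community, where no code exists. A community DVT is asserted when three
  reimbursements occur in order: an echo-Doppler exam at a date T0, a
  delivery of low-molecular-weight heparin or fondaparinux within
  `heparin_window_days` of T0, and a delivery of a vitamin K antagonist
  (VKA) within `vka_window_days` after T0.

PE is assumed to be always hospital-managed, so the algorithm targets DVT
only. The pipeline then adjudicates events, estimates annual incidence per
100 000 with national extrapolation, and summarises 12-month recurrence and
all-cause mortality.

## Case finding and adjudication

All windows are whole days with inclusive endpoints; reimbursement data
carry dates, not times, so same-day ties are meaningful and allowed.

**Community algorithm.** For each echo-Doppler claim at T0 not already
inside a detected episode, an event is emitted iff a qualifying heparin
delivery exists in `[T0 - h, T0 + h]` (default `h = 7`) and a VKA delivery
in `[T0, T0 + v]` (default `v = 7`) with dates ordered
echo ≤ heparin ≤ VKA. The ordering requirement makes the effective heparin
window `[T0, T0 + h]`; the symmetric window is retained as a configurable
rule because the delivery date of the *prescription* may precede the exam
in routine data, and users can widen it. The phrase "within 7 days after
T0" was chosen for the VKA criterion (rather than "at about day 7")
because VKA therapy is routinely started overlapping heparin; the window
is a parameter, so the alternative reading is one flag away. After an
episode is detected at T0, further echo claims within `v` days are treated
as imaging of the same episode and do not start a new event.

**Adjudication.** Events from the two finders are merged and:

1. persons under `adult_age_min` (default 18) at the event date are
   dropped, as are events dated after death;
2. *clot migration*: a DVT (either setting) followed by a PE within
   `migration_window_days` (default 30) collapses into that PE — the
   episode is counted once, as PE;
3. *setting reclassification*: a community DVT followed within
   `comm_to_hosp_window_days` (default 30) by a hospital DVT stay becomes a
   single hospital-managed DVT that keeps the earlier (community) index
   date;
4. same-day ties resolve as PE > hospital DVT > community DVT.

Rules 2 and 3 are applied in that order. Neither window is dictated by the
clinical definitions; 30 days is the span in which a second claim is more
plausibly the same episode's care than a new thrombotic event, and both are
configurable. The **event table** keeps every adjudicated event (one person
can contribute several — incidence counts events), while the **cohort**
takes each person's first in-window event as index — follow-up analyses
count patients. This distinction is what reconciles an event-based
incidence table with a patient-based follow-up table.

**Recurrence blanking.** An adjudicated event within
`recurrence_gap_days` (default 30) of the index is treated as same-episode
care, not recurrence; recurrences are events in
`(index + gap, index + followup_days]`, truncated at death. A gap of 0
reproduces the permissive convention in which even immediate repeat events
count.

## Incidence estimation

With `E` events over `y` years in a population of `N` adults, the annual
rate per 100 000 is `r = (E / y) / N × 1e5`. The 95% interval treats the
annualised count `E / y` as Poisson:

```
r ± 1.96 · sqrt(E / y) / N × 1e5
```

This form reproduces the reference worked example exactly: 675 PE events
over two years in 525 430 adults give 64.2 [57.4–71.1] per 100 000, and
the analogous DVT rows (673 and 586 events) give 64.0 [57.2–70.9] and
55.8 [49.4–62.1]. The denominator is the count of adults covered at the
study midpoint — the simplest population-at-risk convention for a closed
two-year window; there is no person-time adjustment for mid-period entry
or exit (a deliberate non-goal). Extrapolated national counts multiply the
*unrounded* rate by the national population (default 65 026 885) and round
last, which minimises compounding of rounding errors; all-DVT and all-VTE
rows are sums of their components, exact for counts and extrapolations.

## Follow-up statistics

* Proportions carry Wald 95% intervals, clamped to `[0, 100]`%.
* Group homogeneity of recurrence uses Pearson's chi-square **without**
  continuity correction — the uncorrected statistic is what reproduces the
  reference p-value (0.019) on the published 2×3 recurrence table.
* The type-of-recurrence cross-table, whose cells are small, uses Fisher's
  exact r×c test (two-sided by the "probability ≤ observed" convention,
  which is the standard r×c generalisation; tail-ordering alternatives
  exist only for 2×2). A guard (`max_total = 500`) refuses tables too
  large for exact mode rather than silently switching method.
* Cumulative incidence of first recurrence and of death uses the
  Kaplan-Meier product-limit estimator with Greenwood ("plain") intervals,
  reported at days 30, 91, 182, 273 and 365 (months 1, 3, 6, 9, 12).
  Deaths censor the recurrence curve; subjects alive and event-free censor
  at day 365. Whether the reference analysis censored or ignored deaths is
  not stated; censoring is the defensible default, and with
  twelve-month mortality near 6% the difference is small. No
  competing-risks estimator is provided (a non-goal: the method being
  mirrored is plain KM).

## Risk-factor models

Both models follow a **single** univariate-screen-then-multivariate pass:
every candidate covariate is tested alone; those with p < 0.05 enter one
multivariate model; there is no stepwise iteration beyond that. Covariates
are 12-month lookback flags (prior hospitalisation, surgery, trauma, hip
fracture, cancer, obesity, pregnancy, heart failure, renal disease,
gastro-intestinal haemorrhage, hormonal therapy) plus demographics. The
hospitalisation-history covariate exists in two horizons — 12 months
(`prior_hospitalisation`) and 90 days (`prior_hospitalisation_90d`) —
because both appear in the motivating analysis's description; both are
screened.

* **Recurrence**: Cox proportional hazards on days to first recurrence,
  deaths and end of follow-up censoring. Ties are handled by **Breslow**'s
  approximation by default: day-granular claims data produce many ties and
  Breslow is the simplest well-defined choice; Efron is available via the
  `ties` argument.
* **Hospitalisation of DVT**: logistic regression (hospital vs community
  management) among DVT patients.

Inference is Wald throughout (point estimate, 95% CI, p), matching the
reporting style being mirrored. Zero-variance covariates are dropped with a
message; separation raises an error rather than returning an absurd
estimate; Cox non-convergence is flagged, never silent.

## The synthetic claims generator

Real claims extracts of this kind are access-restricted, so the package
ships a generator whose output has the statistical structure the analysis
assumes, with the ground truth retained. Its defaults are the study
conditions, not tuning knobs:

* first-event rates 64.2 / 64.0 / 55.8 per 100 000 adult person-years (PE,
  hospital DVT, community DVT);
* 12-month recurrence probabilities 0.076 / 0.044 / 0.044 and death
  probabilities 0.077 / 0.093 / 0.009, by index category;
* the type of a recurrence follows the published conditional distribution
  given the index category;
* population mixture: 80% adults, ages normal(65, 18) clipped to 18–99
  (matching the reported cohort mean ± SD and range), minors uniform 0–17,
  52% female.

Event times are uniform over the two-year window (only annual aggregates
are reported by the source, so no seasonality is modelled). Community
episodes emit the claim triplet at configurable lags (defaults 2 and
5 days, inside the detection windows) with probability
`triplet_compliance`; incomplete episodes drop one anticoagulant claim and
are invisible to the algorithm *by design*, which is how detection
sensitivity is stressed. Noise consists of echo-only (surveillance
imaging) and heparin-only (prophylaxis) claims at configurable
per-person-year rates — the two clinically plausible confounder patterns —
and never includes VKA, so noise alone cannot complete a triplet.
Risk-factor flags are independent Bernoulli draws for event persons,
materialised as lookback stays/claims, with optional multiplicative
effects on the recurrence hazard and on the hospital-vs-community odds so
the regression stage has a recoverable signal.

Two details matter for exactness. Death dates are drawn per index category
and *clip* emitted claim dates: an episode whose heparin or VKA delivery
would fall after death has those claims dated at the death date instead of
dropped, preserving the echo ≤ heparin ≤ VKA ordering. This keeps the
perfect-recovery property — with full compliance and zero noise the
community finder recovers the truth log with sensitivity and precision
exactly 1 — unconditionally, rather than up to rare death-in-episode
events. Second, recurrences detected inside the study window also enter
the incidence event table (one patient, several events), so recovered
rates sit 2–3% above the configured *first*-event rates; this mirrors the
event-counting convention of the reference table and is well inside the
3-Wald-SE recovery band used in testing.

All randomness flows from one integer seed; stage `k` of the generator
(population, truth, claims, noise) seeds with `seed + k`, so stages are
individually reproducible and a full dataset is byte-identical across
runs.

What the generator does **not** emulate: real drug/procedure coding
systems (service classes are pre-mapped enum labels), age- or
season-specific hazards, correlated comorbidity, coding errors in hospital
diagnoses, and background (non-VTE) mortality. Passing tests on this
generator therefore demonstrate that the *pipeline logic* is correct under
the stated assumptions — not that the algorithm's sensitivity on real
claims is 1, which depends on prescriber behaviour the generator
idealises.

## Numerical and degenerate-input choices

* Ages are completed years at the index date (the alternative —
  age at year start — is not used; the source does not state its choice).
* ICD-10 matching is exact on the expanded code set; range tokens like
  `"I80.1-9"` expand once, and expansion is idempotent.
* Zero-event incidence returns rate 0 with interval clamped at 0; empty
  cohorts yield an empty report with notices instead of errors; a
  contingency table with a zero margin is an error for the chi-square
  (expected counts would be 0) but p = 1 for Fisher (only one table has
  those margins).
* Sizes used in the shipped checks: rate-recovery runs use 60 000-person
  simulations across five seeds, the end-to-end recovery run 500 000
  persons, and the null-calibration check 200 replicates of a
  1 804-patient cohort — large enough that 3-SE bands are a few per
  100 000 while a full check run stays under a minute.

## Limitations

The pipeline inherits the epistemic limits of claims data: undiagnosed or
untreated VTE is invisible; immediately fatal PE never reaches a hospital
code; cause of death is absent, so "mortality" is all-cause only. The
incidence denominator is a single mid-study population count, crude (no
age/sex standardisation). The Fisher test is exact-enumeration only; very
large sparse tables need a Monte-Carlo mode that is deliberately out of
scope.
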