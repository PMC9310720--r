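---
title: "Methods: registry-based burden analysis of incident MDD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry-based burden analysis of incident MDD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddburden)
library(data.table)
```

This vignette documents the models and procedures implemented in
`mddburden`, the assumptions behind them, and the design choices made where
registry practice leaves the construction open.

## The measurement problem

Administrative healthcare data never observe a depressive episode directly;
they observe *contacts*: diagnosis codes, pharmacy dispensations, procedure
codes, visits, admissions, and insurance spells. Everything in this package
is an operationalization of clinical concepts in terms of such contacts. Two
consequences follow and should frame any interpretation:

* an "episode" here is the span of healthcare activity related to MDD, a
  proxy that tends to *overestimate* the symptomatic episode (treatment
  continues past remission) and can miss untreated illness entirely;
* every concept is code-defined, so the `mdd_codebook` is configuration,
  not truth. The shipped defaults (F32/F33 for MDD; F20–F29, F30, F31,
  F00–F03 for the unipolarity exclusions; N06A for antidepressants; the five
  add-on drugs; conventional choices for the comorbid conditions) are
  editable via `load_codebook()`, and every algorithm is driven by the
  concept, not the code list.

## Episode construction

`build_episodes()` scans a person's depressive events from the first-ever
MDD diagnosis (the index). The tunable parameters, all in days:

| parameter | default | meaning |
|---|---|---|
| `gap_days` (G) | 365 (sensitivity: 180) | largest inter-event gap that keeps an episode ongoing |
| `extension_cap_days` | 100 | cap on the supply extension when a dispensation closes an episode |
| `tablets_per_day` | 1 | tablets-to-days conversion for supply |

Rules, in the order they apply:

1. same-day records collapse to one event day that keeps a diagnosis flag
   (may start an episode), a dispensation flag (may extend one) and the
   summed tablet count — so mixed same-day records lose neither role;
2. a gap ≤ G continues the episode; a gap > G closes it at the last event;
3. a closing dispensation extends the end by `min(floor(tablets /
   tablets_per_day), extension_cap_days)` days;
4. after closure, only an MDD *diagnosis* starts the next episode —
   dispensations and procedures between episodes are ignored;
5. an episode whose last event lies within G of the data end cannot be
   distinguished from a continuing one and is marked `open_at_data_end`
   (treated as right-censored downstream, with no supply extension).

Gap checks use raw event dates; whether the original construction carried
dispensation dates forward by their supply before the gap check is ambiguous
in prose descriptions of this design, so a `supply_extended_gaps` flag
provides the alternative (default off — the literal reading). The flag can
merge episodes that the literal rule splits; it never splits what the
literal rule merges.

Correctness is established two ways: hand-traced fixtures (including a
stream where the gap rule closes episodes at d300 and d700 and an
inter-episode dispensation is ignored), and exact equivalence with an
independent brute-force day-grid flood-fill oracle on 1,000 random event
streams at both G settings.

Episode duration is analysed only for persons with ≥ 365 days of follow-up
(otherwise an end date cannot be assigned), by Kaplan–Meier via
`survival::survfit` with Greenwood variance and log–log confidence bands;
the median is the smallest t with S(t) ≤ 0.5 (Brookmeyer–Crowley CI). KM is
standard machinery and deliberately not re-implemented.

## Cohort, matching and censoring

* **Incidence**: first-ever MDD diagnosis inside the inclusion window
  (default 2012-01-01 to 2018-12-31). Age at index is
  `floor((index − birth) / 365.25)` whole years. When the index day carries
  several care levels, psychiatric > primary > other (specialist recording
  treated as authoritative); the rule is configurable by editing the
  diagnosis stream.
* **Exclusions**: any psychosis/bipolar/mania/dementia code dated ≤ index
  (full-lookback "history", distinct from the 5-year descriptive lookback),
  and failure of continuous residency over `[index − 365, index]`.
* **Controls**: eligibility demands no depression diagnosis, self-harm code
  or antidepressant dispensation *anywhere in the data window* (an any-time
  rule), plus the case exclusions evaluated at the index date, plus being
  alive and resident then. Sampling is uniform within the sex ×
  municipality × age ± 2y stratum, with replacement, seeded; the uniform
  rule is a documented choice — registry descriptions rarely state the
  sampling scheme. Unmatched cases are kept and flagged, not dropped.
* **Censoring**: follow-up ends at the earliest of death, emigration (end
  of the residency interval containing index), first post-index exclusion
  diagnosis, or end of data; date ties resolve death > emigration >
  exclusion. Zero-length follow-up is clamped to 0.5 day rather than
  dropped, so same-day deaths stay in the risk set.

## Trajectories

Months are *calendar* months anchored at the index month (month 0 contains
the index date), not 30-day bins. A dispensation covers
`ceil(days_supplied × 1.25)` days from its fill date — the 25% adherence
buffer; fractional days round *up* (favouring coverage; configurable). A
month counts as drug-treated when any coverage window intersects it, and as
procedure-treated when a procedure record is dated inside it.

Cumulative ("ever treated") curves carry a person forward from the first
treated month. The denominator for cumulative curves is the full cohort
(fixed N), which makes the curve monotone by construction — the property a
cumulative-inclusion analysis is meant to have; with an at-risk denominator
the curve can dip when treated persons are censored. Because the
denominator convention is genuinely open, `proportion_series(...,
denominator = "at_risk")` exposes the censoring-adjusted variant, and point
(currently-treated) curves always use at-risk denominators.

Comorbidity accumulation admits diagnoses from a 5-year pre-index lookback:
a person counts from `max(−12, month of first qualifying diagnosis)`;
records older than the lookback never qualify, so the month-0 value matches
the baseline-table convention.

## Burden estimation

Monthly series use interval overlap: bed days are the overlap of the
half-open stay with the month; work-loss days are overlap × spell extent;
sick-leave spells under 14 days are dropped (employer-paid), and work-loss
analyses are restricted to ages 20–64 at index.

Annual estimates use day-based windows — pre `[index − 365, index)`, post
`[index, index + 365)` — while the figures use calendar months; the dual
convention is intentional and documented. Each person contributes a total
`x_i` and a weight `w_i` = followed days / 365 (pre-index windows are fully
observed by the residency requirement; 365-day years are the default, with
`days_per_year` configurable since the original convention is unstated).
The estimator is the ratio `mu = Σx / Σw` with linearized sandwich standard
error `sqrt(Σ(x_i − mu·w_i)²) / Σw`, equivalent to an intercept-only
weighted regression with heteroskedasticity-robust errors. The test suite
verifies |bias| < 1% and 93–97% CI coverage over 500 replicates of
Poisson(λ·w) outcomes with Beta-distributed weights at n = 1,000.
Presentation ratios round half away from zero to one decimal.

## Mortality

`fit_cox()` maximizes the Cox partial likelihood for the single binary
case/control covariate by Newton–Raphson (convergence: log-likelihood change
< 1e-9, ≤ 50 iterations, damped early steps), with Efron ties by default
(better at day granularity with many ties) and Breslow available. The fit is
unstratified — the crude case-versus-control contrast; whether the original
matched design should be respected in the variance is left to the analyst
(pairs are carried in the records). With all events in one group the
likelihood is monotone and the fit is flagged rather than returning a
spurious number. Equivalence with `survival::coxph` to 1e-6 in the log
hazard ratio is asserted on 100 random datasets in the acceptance suite —
the reference implementation serves as oracle only.

## Referral flows

States at index + {0, 91, 182, 273, 365} days (3-month grid, 91 ≈ 365/4,
configurable) are the care level of the most recent depressive event dated
on or before the timepoint. Dispensations carry no care level and never
change the state — the natural reading, since a pharmacy fill says nothing
about the treating level. Once censored, always censored. The summary
"share of primary-index cases reaching psychiatric care within the first
year" is event-based by default (any psychiatric-level depressive event in
days 1–365, among primary-index cases still followed at month 12); a
state-based variant is available and can only be lower.

## The synthetic registry

`generate_registry()` emulates the *structure* the analysis assumes — not
any real population's joint distributions. Its defaults encode the study
conditions the pipeline targets: a 2010–2019 window with 2012–2019
inclusion; 63.2% women among onsets (via sex-specific onset hazards over a
50/50 population); index care-level mix 68.2/27.3/4.6; log-normal true
episode duration (median 398 days, σ = 0.6); onset rate 0.0082/year;
pre-index antidepressant use calibrated to ≈ 26% of cases; a 13.8%
primary-to-psychiatric referral propensity in year one; control mortality
5.4 per 1000 person-years with a case log-hazard increment of log(2.2) —
so the pooled death rate is ≈ 8.6 per 1000 person-years, consistent with a
cohort of this composition; visit, bed-day and work-loss rates set to give
case/control contrasts of the magnitude seen in incident-MDD cohorts.

Structural guarantees that make recovery tests meaningful:

* randomness is counter-based (`hash_unif`, a splitmix64 stream keyed by
  seed × person × draw counter), so the seed fully determines the output and
  adding persons never perturbs existing ones;
* in-episode diagnosis gaps follow a truncated-exponential renewal (mean
  120 d, truncated to [7, 350] d) and a terminal contact is placed at the
  true episode end, so no within-episode gap exceeds 350 days: the 365-day
  rule must recover true episodes (the suite demands ≥ 99% day coverage),
  while the 180-day rule must split some of them (the sensitivity check);
* deaths are piecewise-exponential with the hazard multiplied by
  `exp(case_log_hr)` from onset, and `simulate_matched_survival()` draws the
  same mortality model directly (uniform entry over 7 years, administrative
  end censoring, emigration 0.15/year giving ≈ 2.5-year mean follow-up) for
  hazard-ratio recovery at scale.

What passing these tests does **not** show about real data: coding
practice drift, care-level misclassification, partial capture of private
caregivers, informative censoring, age-dependent mortality and morbidity,
and recurrent (multi-episode) histories are all absent from the generator;
the pipeline's behaviour under those realities must be judged separately.

## Numerical conventions

* All intervals are half-open `[start, end)`; dates are ISO-8601 with no
  times of day; a one-day event is `[d, d + 1)`.
* Supply days round up (`ceiling`); presentation rounding is half away from
  zero; ages floor to whole years with 365.25-day years.
* Emigration day is the last resident day (residency end − 1).
* `weighted_annual_mean` refuses `Σw = 0` and n < 2; `burden_ratio` refuses
  a zero reference; degenerate Cox inputs error (`no events`) or flag
  monotone likelihoods.

## Problem sizes

The shipped test and acceptance runs use desk-scale sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: registry simulations
of 4,000–20,000 persons for pipeline checks, 12,000 persons (high onset
rate) for duration recovery, 50,000 matched pairs × 20 seeds for
hazard-ratio recovery, 1,000 random streams for the episode oracle, and 500
replicates for estimator calibration. The `analysis/` workflow runs at
20,000 persons.

## Known limitations

* Single-episode generator: recurrence analysis (ordinal > 1 episodes) is
  implemented and tested on fixtures but not exercised by simulation truth.
* No age- or calendar-dependence in the synthetic hazards.
* BMI and smoking fields of baseline description are out of scope (free-text
  EMR extraction), as is health-economic costing and cause-of-death
  analysis.
* The quetiapine add-on rule reads the *prescribed daily dose*; dispensations
  lacking it are conservatively excluded from the add-on set. Whether
  dispensed strength was the original discriminator cannot be settled from
  code lists alone.
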