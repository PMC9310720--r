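# mddburden

Registry-based estimation of the clinical and societal burden of incident
major depressive disorder (MDD).

Regional healthcare registries record MDD only as scattered events — ICD-10
diagnoses, antidepressant dispensations, procedure codes, visits, admissions,
sick-leave spells. This package turns such event tables into the quantities a
pharmacoepidemiologist reports for an incident-MDD cohort and its matched
population controls: treatment-episode durations, monthly treatment and
comorbidity trajectories, healthcare-resource-utilization and work-loss
burden, all-cause mortality, and care-level referral flows. It is written for
epidemiologists and biostatisticians who work with Nordic-style linked
registry data (or need a faithful synthetic stand-in for it).

## What it computes

**Treatment episodes.** A person's depressive events are the union of MDD
diagnoses (F32/F33, any care level), antidepressant dispensations (ATC N06A),
add-on medication dispensations (lithium, risperidone, olanzapine,
aripiprazole, quetiapine at prescribed daily dose > 100 mg), and ECT / rTMS /
psychotherapy procedures. Starting from the first-ever MDD diagnosis (the
index date), consecutive events with gaps ≤ G days (G = 365; sensitivity
G = 180) form one episode; a larger gap closes the episode at its last event,
and when that event is a dispensation the end is extended by the dispensed
tablets as days of supply, capped at 100 days. Only a subsequent MDD
*diagnosis* opens the next episode. Episode duration is summarized by
Kaplan–Meier among cases with ≥ 1 year of follow-up.

**Cohort.** Incident cases are first-ever F32/F33 diagnoses in the inclusion
window, with no psychosis (F20–F29), bipolar (F31), mania (F30) or dementia
(F00–F03) history and ≥ 12 months of prior residency. Each case draws one
control, with replacement, from the same sex × municipality × age (±2 years)
stratum among persons with no depression, self-harm or antidepressant
records; controls inherit the case's index date. Follow-up ends at the first
of death, emigration, a post-index exclusion diagnosis, or end of data.

**Burden.** Monthly means over months −12..+12 from the index month, and
annualized means over the 365-day windows before/after index using the
follow-up-weighted ratio estimator

    mu = sum(x_i) / sum(w_i),   se = sqrt(sum((x_i − mu·w_i)^2)) / sum(w_i)

where `x_i` is a person's outcome total and `w_i` the followed fraction of
the window — a linearized (sandwich) standard error that respects the
person-level clustering of the monthly data.

**Mortality.** An in-package Newton–Raphson Cox partial-likelihood fit
(binary case/control covariate, Efron or Breslow ties), cross-checked in the
test suite against `survival::coxph` to 1e-6.

**Synthetic registry.** `generate_registry()` emits all seven tables with
known ground truth (latent onsets, true episode intervals, a true mortality
hazard ratio) from counter-based per-person random substreams, so every
pipeline stage can be validated by parameter recovery. It is a structural
emulation, not a reproduction of any real population.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions
(`Rscript analysis/01_simulate.R`, then `02_cohort.R`, … `07_referrals.R`),
writing its tables under `results/`. With the shipped configuration (seed
2026, 20,000 persons) it prints:

```
simulated 20000 persons, 1221 latent MDD onsets (62.5% female onsets)
true episode duration: median 396 days

incident cases: 909; matched: 100.0%
care level at index: primary 67.7%, psychiatric 27.4%, other 5.0%
women among cases: 62.8%; mean (SD) age 44.1 (16.9)

gap rule 365 days: 763 analysed cases, median episode 438 days (95% CI 403-465)
gap rule 180 days: 763 analysed cases, median episode 294 days (95% CI 276-317)

any therapy: 0.6% at month -12, 25.0% the month before index, 61.2% in the index month
ever treated by month +12 (cumulative): 83.7%

outpatient visits, pre-index: cases 2.3x controls
outpatient visits, post-index: cases 2.8x controls

Cox fit (efron ties): n = 1818, events = 64
HR 2.37 (95% CI: 1.39-4.05)

primary-index cases reaching psychiatric care within 12 months: 14.4%
```

Reading these numbers: the cohort builder recovers the generator's design
(63% women, 68/27/5 care mix); the 180-day sensitivity rule shortens the
median episode, as the gap construction implies; the Cox estimate brackets
the generator's true hazard ratio of 2.2 at this desk-scale event count
(64 deaths); and the referral share approaches the configured 13.8%
propensity. At 50,000 matched pairs (the acceptance setting below) the Cox
estimate tightens to ≈ 2.2–2.3.

A direct API session:

```r
library(mddburden)
sim <- generate_registry(sim_config(seed = 7, n_persons = 5000))
cb  <- default_codebook()
coh <- build_cohort(sim$tables, cb, seed = 7)
eps <- cohort_episodes(coh$members, sim$tables, cb)
dur <- episode_durations(eps, coh$members[group == "mdd"])
km_fit(dur$duration_days, dur$observed)
#> Kaplan-Meier fit: n = 197, events = 152
#> median 404 days (95% CI: 372-443)
```

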