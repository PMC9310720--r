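#!/usr/bin/env Rscript
# Stage 3 — MDD treatment episodes and Kaplan-Meier duration.
#
# Stitches each case's depressive events (diagnoses, antidepressant and
# add-on dispensations, ECT/rTMS/psychotherapy) into episodes with the
# maximum-gap rule, then estimates the incident-episode duration by
# Kaplan-Meier among cases with at least one year of follow-up. The 180-day
# sensitivity rule is run alongside the 365-day main analysis.
source(file.path("analysis", "00_common.R"))

tabs <- registry()
cb <- default_codebook()
members <- read_members()
cases <- members[group == "mdd"]

for (G in c(CFG$gap_days, 180L)) {
  eps <- cohort_episodes(members, tabs, cb, episode_params(gap_days = G))
  dur <- episode_durations(eps, cases)
  km <- km_fit(dur$duration_days, dur$observed)
  tag <- paste0("g", G)
  save_csv(eps, paste0("episodes_", tag))
  save_csv(data.table(t = km$time, S = km$surv, n_risk = km$n_risk,
                      ci_low = km$ci_low, ci_high = km$ci_high),
           paste0("km_", tag))
  message(sprintf("gap rule %d days: %d analysed cases, median episode %s days (95%% CI %s-%s)",
                  G, km$n, format(km$median), format(km$median_ci[1]),
                  format(km$median_ci[2])))
}
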