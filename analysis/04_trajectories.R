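#!/usr/bin/env Rscript
# Stage 4 — monthly treatment-exposure and comorbidity trajectories.
#
# For months -12..+12 around the index month: the share of cases with ongoing
# antidepressant therapy per therapy (dispensation coverage with the 25%
# adherence buffer; procedure codes by month), the cumulative ever-treated
# curves, and cumulative psychiatric-comorbidity prevalence with the 5-year
# lookback.
source(file.path("analysis", "00_common.R"))

tabs <- registry()
cb <- default_codebook()
members <- read_members()

grid <- monthly_exposure(members, tabs, cb)
pt <- proportion_series(grid, "point")
cm <- proportion_series(grid, "cumulative")
co <- comorbidity_series(members, tabs, cb)

save_csv(pt, "exposure_point")
save_csv(cm, "exposure_cum")
save_csv(co, "comorbidity_cum")

any_pt <- pt[therapy == "any"]
message(sprintf("any therapy: %.1f%% at month -12, %.1f%% the month before index, %.1f%% in the index month",
                100 * any_pt[m == -12, proportion],
                100 * any_pt[m == -1, proportion],
                100 * any_pt[m == 0, proportion]))
message(sprintf("ever treated by month +12 (cumulative): %.1f%%",
                100 * cm[therapy == "any" & m == 12, proportion]))
for (cond in c("anxiety", "stress"))
  message(sprintf("%s: cumulative %.1f%% at month -12 vs %.1f%% in the index month",
                  cond, 100 * co[condition == cond & m == -12, proportion],
                  100 * co[condition == cond & m == 0, proportion]))
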