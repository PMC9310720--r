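#!/usr/bin/env Rscript
# Stage 5 — healthcare utilization and work-loss burden.
#
# Monthly mean outpatient physician visits, inpatient bed days and work-loss
# days (cases vs matched controls), and the annual follow-up-weighted means
# with robust 95% CIs over the 12 months before/after index, plus the
# case/control ratios.
source(file.path("analysis", "00_common.R"))

tabs <- registry()
members <- read_members()

save_csv(monthly_hru(members, tabs), "monthly_hru")
save_csv(monthly_workloss(members, tabs), "monthly_workloss")

tab <- burden_table(members, tabs)
save_csv(tab, "burden_table")

# rare outcomes can have a zero control mean at desk scale; skip those ratios
ratios <- tab[, .(ratio = if (estimate[group == "control"] > 0)
                    burden_ratio(estimate[group == "mdd"],
                                 estimate[group == "control"]) else NA_real_),
              by = .(outcome, window)]
save_csv(ratios, "burden_ratios")

for (w in c("pre", "post")) {
  r <- ratios[outcome == "visits_total" & window == w, ratio]
  message(sprintf("outpatient visits, %s-index: cases %.1fx controls", w, r))
}
message(sprintf("work loss, post-index: cases %.1fx controls",
                ratios[outcome == "workloss_total" & window == "post", ratio]))
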