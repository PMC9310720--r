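#!/usr/bin/env Rscript
# Stage 6 — all-cause mortality.
#
# Cox proportional-hazards contrast (cases vs matched controls, Efron ties)
# on follow-up from index to death or censoring, plus crude mortality rates
# per 1000 person-years.
source(file.path("analysis", "00_common.R"))

members <- read_members()
rec <- survival_table(members)
fit <- fit_cox(rec, ties = "efron")
rates <- mortality_rate(rec)

save_csv(rates, "mortality_rate")
jsonlite::write_json(
  list(log_hr = fit$log_hr, se_log_hr = fit$se_log_hr, hr = fit$hr,
       ci95 = fit$ci95, n = fit$n, n_events = fit$n_events, ties = fit$ties),
  file.path(CFG$results_dir, "cox.json"), auto_unbox = TRUE, digits = NA)

print(fit)
message(sprintf("mortality rate, all: %.1f per 1000 person-years",
                rates[group == "all", rate_per_1000py]))
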