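#!/usr/bin/env Rscript
# Stage 2 — incident cohort with matched controls.
#
# First-ever MDD diagnoses inside the inclusion window form the index events;
# unipolarity and 12-month-residency exclusions apply; each case draws one
# control (with replacement) from the sex x municipality x age(+-2y) stratum
# of persons with no depression, self-harm or antidepressant records.
source(file.path("analysis", "00_common.R"))

tabs <- registry()
cb <- default_codebook()
coh <- build_cohort(tabs, cb, seed = CFG$seed)

save_csv(coh$members, "cohort_members")
save_csv(coh$pairs, "cohort_pairs")

n_cases <- nrow(coh$cases)
match_rate <- mean(!is.na(coh$pairs$control_id))
message(sprintf("incident cases: %d; matched: %.1f%%", n_cases, 100 * match_rate))
message("care level at index:")
print(coh$cases[, .N, by = care_level_at_index][, pct := round(100 * N / sum(N), 1)][])
message(sprintf("women among cases: %.1f%%; mean (SD) age %.1f (%.1f)",
                100 * mean(coh$cases$sex == "F"),
                mean(coh$cases$age_at_index), sd(coh$cases$age_at_index)))
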