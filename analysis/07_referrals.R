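#!/usr/bin/env Rscript
# Stage 7 — referral flows between healthcare levels.
#
# Classifies each case at 0/3/6/9/12 months after index by the care level of
# the most recent depressive event, counts the transitions between
# consecutive timepoints (the alluvial table), and reports the share of
# primary-care-index cases reaching psychiatric care within the first year.
source(file.path("analysis", "00_common.R"))

tabs <- registry()
cb <- default_codebook()
members <- read_members()

st <- referral_states(members, tabs, cb)
fl <- flow_table(st, members, tabs, cb)

save_csv(st, "referral_states")
save_csv(fl$flows, "referral_flows")
jsonlite::write_json(
  list(share_primary_to_psychiatric = fl$share_primary_to_psychiatric),
  file.path(CFG$results_dir, "referral_summary.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("primary-index cases reaching psychiatric care within 12 months: %.1f%%",
                100 * fl$share_primary_to_psychiatric))
message("state distribution at month 12:")
print(st[timepoint == 12, .N, by = state][order(-N)])
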