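# Example codebook override. Any subset of the default code sets may be
# redefined; ranges like "F20-F29" expand to 3-character stems, and a set may
# be given as include/exclude lists. Unlisted entries keep package defaults.
mdd:
  - F32
  - F33
psychosis: F20-F29
quetiapine_min_daily_dose_mg: 100
comorbidities:
  stress:
    include: F43
    exclude: F431
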