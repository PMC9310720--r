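# Shared settings for the numbered analysis scripts.
seed: 2026
n_persons: 20000
gap_days: 365
registry_dir: results/registry
results_dir: results
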