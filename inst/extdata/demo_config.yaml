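# Small demonstration cohort (completes in about two minutes on one CPU).
# Any key from vrgaze::default_config() may be overridden here.
seed: 11
n_adhd: 12
n_control: 12
n_scenarios: 3
scenario_duration_s: 25
instruction_duration_s: 5
outer_folds: 6
inner_folds: 2
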