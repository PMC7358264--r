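# Reference small-trial scenario: 48 patients, ten sites, three rounds,
# two atypical sites shifted upward by 2 outcome standard deviations.
n_total: 48
n_sites: 10
n_rounds: 3
atypical_shifts:
  "1": 2.0
  "2": 2.0
mu_normal: 0.0
outcome_sd: 1.0
n_reps: 100
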