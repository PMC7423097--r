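# Example synthetic-cohort configuration. All dispersion values are
# synthetic conventions (the published analysis is mean-based); the
# participation rates are the published program statistics.
n_patients: 500
seed: 20180101
duration_jitter: 0.2
transport_minutes:
  mean: 52.5
  sd: 15
wage_cv: 0.2
pain:
  pre_mean: 5.7
  pre_sd: 2.0
  post_mean: 3.2
  post_sd: 2.0
participation_rates:
  exercise_session: 0.60
  copatient_lecture: 0.44
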