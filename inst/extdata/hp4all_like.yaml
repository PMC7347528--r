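name: hp4all_like
definition:
  n_predictors: 50
  n_awareness: 26
  target_max_score: 98
  seed: 101
  n_second_trimester: 3
  n_multiparous_only: 5
  cutoff: 16
config:
  n_participants: 1752
  prevalences:
  - 0.0475
  - 0.0437
  - 0.0094
  - 0.009
  - 0.004
  - 0.0693
  - 0.0881
  - 0.0244
  - 0.2172
  - 0.0357
  - 0.0123
  - 0.0853
  - 0.1169
  - 0.0208
  - 0.0274
  - 0.2272
  - 0.2044
  - 0.004
  - 0.004
  - 0.0334
  - 0.3
  - 0.105
  - 0.0445
  - 0.0289
  - 0.0785
  - 0.039
  - 0.1308
  - 0.0879
  - 0.0267
  - 0.0354
  - 0.0128
  - 0.0138
  - 0.1046
  - 0.3
  - 0.0481
  - 0.0432
  - 0.0229
  - 0.0341
  - 0.0169
  - 0.0513
  - 0.0852
  - 0.018
  - 0.0225
  - 0.0141
  - 0.0086
  - 0.0414
  - 0.0209
  - 0.0321
  - 0.0648
  - 0.0537
  correlation: 0.1
  pair_correlations:
  - item1: pred_28
    item2: pred_07
    rho: 0.85
  - item1: pred_41
    item2: pred_30
    rho: 0.85
  target_outcome_rate: 0.16
  beta_per_point: 0.06
  extra_item_betas:
    pred_16: 0.65
    pred_28: 1.0
    pred_41: 1.0
    pred_40: 0.9
    pred_10: 1.0
    pred_07: -0.35
    pred_30: -0.4
  multiparous_prob: 0.543
  missing_participant_rate: 0.07
  missing_mechanism: MCAR
  item_missing_prob: 0.05
  development_fraction: 0.6667
  seed: 1
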