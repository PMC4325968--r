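# Example pipeline configuration for run_experiment(); unspecified keys fall
# back to pipeline_config() defaults.
n_seizure: 171
n_nonseizure: 171
beta_high: 25
selection:
  method: lda_backward
  k: 20
  max_abs_corr: 0.9
  per_region: 5
smote:
  k: 5
  amount: 100
  mode: pre_split
evaluation:
  train_frac: 0.8
  holdout_reps: 100
  kfold: false
  folds: 5
  kfold_reps: 1
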