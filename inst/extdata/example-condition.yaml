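# Example run configuration (field-for-field mirror of condition_spec;
# omitted fields take the standard defaults).
network:
  n_total: 1200
  ei_ratio: 4
  remove_strong: false
stimulus:
  period_ms: 25      # 40 Hz
  lambda_hz: 1.0
  duration_ms: 7000
sim:
  dt_ms: 0.1
  duration_ms: 7000
  record_from_ms: 3000
n_trials: 10
base_seed: 1
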