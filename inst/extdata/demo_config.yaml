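# Demonstration run: small simulated injection cohort analyzed end to end.
seed: 7
frame_interval: 0.2
denoise: true
nl_filter:
  exponent_p: 5
  n_fa: 1
  f: 2
  n_scales: 4
  m: 10
hmm:
  mu: 1.5
  beta: 0.5
  k_max: 3
  restarts: 3
analysis:
  fret_threshold: 0.5
  frame_ms: 200
  sync_window: 10
  sync_min_residence: 10
injection_time: 10
simulate:
  enabled: true
  kind: injection
  n: 8
  wait_mean: 10.6
  fraction_stable: 0.8
  k_on: 0.1
  k_off: 0.1
  duration: 60
  total_intensity: 1000
  crosstalk_g: 0.07
  fret_noise_sd: 0.08
  donor_bleach_mean: 600
  acceptor_bleach_mean: 600
  n_donor_only: 6
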