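# Minimal end-to-end study on the bundled toy model: one feed-rate factor,
# synthetic data generated at run time.
scenario:
  kind: toy
  args:
    F: 0.3
synthetic:
  kind: toy
calibration:
  free: [k, b]
  n_fits: 8
  n_starts: 1
  maxit: 60
design:
  factors:
    - {name: F, lower: 0.0, upper: 1.2, maps_to: feed.f1.F, units: ml/min}
  k: 15
  n_random: 5000
mc:
  n_sims: 15
response:
  observable: P
  reduction: value_at_time
  at: 24
desirability:
  w1: 0.8
  w2: 0.2
  n_select: 3
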