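# Gulf-of-Mexico female sperm whale reference case (fixture v1).
# Five-stage life cycle: calf, juvenile, mature, mother, post-breeding;
# post-breeders return to the mature stage, fecundity flows 3 -> 1.
vital_rates:
  sigma: [0.9070, 0.9424, 0.9777, 0.9777, 0.9777]
  gamma: [0.4732, 0.1151, 0.2586, 0.4920, 0.4920]
  b: 0.1250
  advance_to: [2, 3, 4, 5, 3]
disturbance:
  epsilon0: 0.05
  t_critical: 10
  t_end: 20
  c1: 2
  c2: 2
  shape: crf
  target: survival
  tm_policy: midpoint
simulation:
  years: 100
  reps: 5000
  seed: 1
  total: 1665
  sex_ratio_female: 0.5
  rule: final
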