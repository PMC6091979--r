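# Blocked detection design: 3 sections x 10 blocks x 40 trials,
# target-present ratios 75/50/25% across sections, dimensions alternating
# between blocks. Generating model: LATER with non-decision time and
# starting-point updating of the response prior with forgetting.
experiment: exp1_detection_blocked
section_order: [0.75, 0.50, 0.25]
n_participants: 12
lapse_rate: 0.015
lapse_rt_range: [0.15, 2.0]
seed: 1
model:
  accumulator: LATER
  nd_time: with
  rdf_level: s0_decay
  tdd_level: no_update
true_params:
  absent.D: 1.0
  absent.mu: 6.5
  absent.sigma: 1.3
  color.D: 1.0
  color.mu: 6.5
  color.sigma: 1.3
  orientation.D: 1.0
  orientation.mu: 6.5
  orientation.sigma: 1.3
  t_er: 0.3
  rdf_alpha: 0.8
  rdf_beta0: 2.0
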