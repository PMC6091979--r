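# Dimension discrimination design: target present on every trial,
# color-target ratios 75/50/25% across sections. Generating model: LATER
# with starting-point updating of the response prior and decaying rate
# updating of the dimension.
experiment: exp2_dimension_discrimination
section_order: [0.75, 0.50, 0.25]
n_participants: 12
lapse_rate: 0.025
lapse_rt_range: [0.15, 2.0]
seed: 2
model:
  accumulator: LATER
  nd_time: with
  rdf_level: s0_decay
  tdd_level: rate_decay
true_params:
  color.D: 1.0
  color.mu: 6.5
  color.sigma: 1.3
  orientation.D: 1.0
  orientation.mu: 6.5
  orientation.sigma: 1.3
  t_er: 0.3
  rdf_alpha: 0.8
  rdf_beta0: 2.0
  tdd_alpha: 0.9
  tdd_delta: 0.1
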