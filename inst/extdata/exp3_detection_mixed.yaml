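# Mixed detection design: 50/50 target presence, dimensions interleaved,
# 65-trial De Bruijn-balanced blocks. Generating model: LATER with
# starting-point updating of the response prior and weighted (shared
# resource) rate updating of the dimension.
experiment: exp3_detection_mixed
n_blocks: 20
n_participants: 12
lapse_rate: 0.033
lapse_rt_range: [0.15, 2.0]
seed: 3
model:
  accumulator: LATER
  nd_time: with
  rdf_level: s0_decay
  tdd_level: rate_weighted
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
  tdd_alpha: 0.9
  tdd_delta: 0.1
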