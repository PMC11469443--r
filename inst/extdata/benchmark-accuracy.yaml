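# Two-state promoter accuracy benchmark configuration: smoothed vs exact
# simulation at the standard settings.
model:
  type: two_state
  params: {konR: 0.5, koffR: 1.0, r: 10.0, gamma: 1.0}
smoothing: {one_over_a: 200, one_over_b: 20}
simulation: {T: 10000, n_traj: 2000, max_steps: 1000000, seed: 1}
output: {dir: accuracy-run}
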