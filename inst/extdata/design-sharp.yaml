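# Four-state promoter design run against the shipped sharp reference target.
target: {reference: sharp, r: 1, c_min: 0.01, c_max: 100, n_points: 10}
design: {engine: exact}
optimizer: {lr: 0.15, iterations: 2000}
simulation: {T: 10, n_traj: 600, max_steps: 1000000, seed: 1}
output: {dir: design-run}
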