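# Demonstration run configuration: simulated 3.0 T survey (preliminaries
# m = 1.06e6 A m^2, h = 1.00 m; true planar offsets 0.69 / 0.08 m) and one
# simulated trial of tasks N1 and N6 per radiographer.
scanner_label: Machine 3.0
moment: 1.06e6
magnet_height: 1.0
true_offsets: [0.69, 0.08]
noise_rel: 0.02
tasks: [N1, N6]
operators: [MRIR1, MRIR2]
n_trials: 1
map_seed: 101
motion_seed: 2025
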