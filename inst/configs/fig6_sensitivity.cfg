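# Global sensitivity of barrier and flux to the labelled pathway connections
schema_version = 1
kind = sensitivity
seed = 1
D_input = 0.95
connections = T21, T31, T42, T53, T45, T75, T47, T57
percent_grid = -50, -40, -30, -20, -10, 0, 10, 20, 30, 40, 50
grid_n = 100
n_snapshots = 120
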