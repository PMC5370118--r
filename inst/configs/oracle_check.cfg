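# Langevin histogram vs mean-field landscape cross-validation
schema_version = 1
kind = oracle_check
seed = 1
D_input = 0.8
projection = 1, 6
grid_n = 50
n_snapshots = 120
duration = 240000
dt = 0.01
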