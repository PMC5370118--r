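# Decoupled DBS (somatic inhibition + efferent activation) of STN
schema_version = 1
kind = dbs
seed = 1
target = STN
mode = decoupled
D_input = 1.10
offsets = 0, -0.3, -0.6, -0.9, -1.2, -1.5, -1.8, -2.1, -2.4
gains = 1, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3, 1.35, 1.4
grid_n = 100
n_snapshots = 120
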