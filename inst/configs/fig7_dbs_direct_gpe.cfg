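# Direct-inhibition DBS of the GPe
schema_version = 1
kind = dbs
seed = 1
target = GPe
mode = direct_inhibition
D_input = 1.10
offsets = 0, -0.15, -0.3, -0.45, -0.6, -0.75, -0.9, -1.05, -1.2
grid_n = 100
n_snapshots = 120
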