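# Mexican-hat landscape and flux arrows in the Parkinsonian regime
schema_version = 1
kind = landscape
seed = 1
D_input = 0.8
projection = 1, 6
grid_n = 200
n_snapshots = 200
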