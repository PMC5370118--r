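# Barrier height, average flux, period and EPR across the oscillatory block
schema_version = 1
kind = dopamine_sweep
seed = 1
D_grid = 0.70, 0.757, 0.814, 0.871, 0.929, 0.986, 1.043, 1.10
projection = 1, 6
grid_n = 200
n_snapshots = 200
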