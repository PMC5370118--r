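# Dopamine phase diagram: mono-stable vs limit-cycle regimes
schema_version = 1
kind = phase_scan
seed = 1
D_grid = 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1.0, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3, 1.35, 1.4
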