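# Example synthetic-deposition scenario: a desk-scale stub (0.5 mm^2 in
# nine tiles) exposed for 24 h to 0.5 mg/m^3 of coarse mineral dust.
true_concentration: 0.5
cmd_um: 3
gsd: 1.5
duration_h: 24
deposition_area_mm2: 0.5
n_tiles: 9
contamination_rate: 0
seed: 7
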