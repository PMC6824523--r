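# Example analysis configuration: field defaults, written out explicitly.
volume_shape_factor: 1.6
dynamic_shape_factor: 1.4
particle_density: 2.0
pixel_side_um: 0.64
min_area_um2: 0.41
max_area_um2: 10000
connectivity: 8
foreground_polarity: bright
count_warning_pm25: 55
count_warning_pm10: 71
deposition_model: settling_plus_diffusion
boundary_layer_mm: 1
pm_convention: sharp
norm_area: analyzed
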