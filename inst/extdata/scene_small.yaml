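# synthetic 10 x 10 m sub-scene configuration (denser weed infestation than
# the 100 x 100 m field default so every cover class is well represented)
field_width_m: 10
field_length_m: 10
row_spacing_m: 0.7
row_direction_deg: 65
weed_patch_density_per_ha: 400
n_frames: 4
gsd_cm: 1.63
seed: 7
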