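name: Olympus PEN E-PM1
focal_length_mm: 14.0
sensor_width_mm: 17.3
sensor_height_mm: 13.0
pixels_x: 4032
pixels_y: 3024
bit_depth: 8
band_centers_nm: [450.0, 530.0, 670.0]
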