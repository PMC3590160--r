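name: mini-MCA-6
focal_length_mm: 9.6
sensor_width_mm: 6.66
sensor_height_mm: 5.32
pixels_x: 1280
pixels_y: 1024
bit_depth: 10
band_centers_nm: [450.0, 530.0, 670.0, 700.0, 740.0, 780.0]
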