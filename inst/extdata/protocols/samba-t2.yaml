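type: samba_t2_protocol
tr: 5000.0
prep_times:
- 12.0
- 25.0
- 50.0
- 75.0
- 100.0
- 200.0
- 400.0
excitation_flip_deg: 90.0
n_interleaves: 5
n_points_per_interleaf: 11393
nsa: 2
fov_mm: 30.0
matrix_size: 160
slice_thickness_mm: 1.0
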