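type: samba_t1_protocol
tr: 14000.0
te: 1.66
n_readouts: 50
readout_spacing: 265.0
inversion_flip_deg: 180.0
excitation_flip_deg: 20.0
inversion_efficiency: 1.0
n_interleaves: 5
n_points_per_interleaf: 3535
nsa: 3
fov_mm: 30.0
matrix_size: 128
slice_thickness_mm: 1.0
first_delay: 265.0
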