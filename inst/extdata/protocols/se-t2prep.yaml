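type: se_t2_protocol
tr: 5000.0
prep_times:
- 12.0
- 25.0
- 50.0
- 75.0
- 100.0
- 200.0
- 400.0
nsa: 2
fov_mm: 30.0
matrix_size: 160
n_phase_encodes: 160
slice_thickness_mm: 1.0
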