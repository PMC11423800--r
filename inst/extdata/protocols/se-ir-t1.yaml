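type: se_ir_protocol
tr: 10000.0
te: 3.61
inversion_times:
- 26.0
- 79.0
- 265.0
- 530.0
- 790.0
- 1050.0
- 1320.0
- 1590.0
- 1860.0
- 2120.0
- 3970.0
- 6610.0
- 9250.0
inversion_efficiency: 1.0
nsa: 3
fov_mm: 30.0
matrix_size: 128
n_phase_encodes: 128
slice_thickness_mm: 1.0
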