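cross	class	count	expected_ratio
Ts65Dn_x_F1B6C3B	wt	407	0.5
Ts65Dn_x_F1B6C3B	Ts65Dn	210	0.5
Ms5Yah_x_F1B6C3B	wt	85	0.5
Ms5Yah_x_F1B6C3B	Ms5Yah	17	0.5
Ts65Dn_x_Ms5Yah	wt	73	0.25
Ts65Dn_x_Ms5Yah	Ts65Dn	50	0.25
Ts65Dn_x_Ms5Yah	Ms5Yah	16	0.25
Ts65Dn_x_Ms5Yah	Ts65Dn/Ms5Yah	46	0.25
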