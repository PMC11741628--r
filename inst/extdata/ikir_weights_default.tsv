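kir	ligand	weight
KIR2DL1	C2	1.0
KIR2DL2	C1	0.5
KIR2DL3	C1	0.75
KIR3DL1	Bw4-80I	1.0
KIR3DL1	Bw4-80T	0.75
KIR3DL2	A3A11	0.25
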