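FAM1	A1	0	0	1	2
FAM1	A2	0	0	2	2
FAM1	U1	0	0	1	1
FAM2	B1	0	0	1	2
FAM2	U2	0	0	2	1
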