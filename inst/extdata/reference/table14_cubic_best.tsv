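property	index	R2	SE	F	A	B	C	D	p	indicator
BP	NE1	0.960	68.219	24.150	462.737	-0.140	0.0002	-3.650E-8	0.0132	Sign
E	NE1	0.953	10.802	20.325	81.066	-0.031	3.562E-5	-5.909E-9	0.0169	Sign
FP	NAE	0.929	46.183	13.124	290.642	-0.001	1.619E-8	-2.743E-14	0.0312	Sign
MR	NISIE	0.952	12.891	26.510	-21.143	0.682	-0.001	5.423E-7	0.0042	Sign
PSA	NSDdegE	0.768	43.294	6.615	44.688	-0.590	0.015	0.000	0.0538	Insign
P	NISIE	0.954	5.701	20.742	-7.565	0.262	-0.0003	1.983E-7	0.0165	Sign
MV	NISIE	0.824	89.344	4.667	-98.771	2.240	-0.004	2.105E-6	0.1189	Insign
MW	NE1	0.963	47.411	26.060	-71.570	0.556	-0.0001	2.011E-8	0.0119	Sign
MW	NISIE	0.962	48.281	25.093	-72.220	2.353	-0.003	1.520E-6	0.0125	Sign
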